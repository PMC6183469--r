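#' Run the full mimicry-cost analysis
#'
#' Executes the complete estimation sequence on a survey:
#' 1. attitude proportions with binomial-GLM uncertainty (mu0 = kill-all,
#'    muv = kill-selective);
#' 2. the called-adder identification GLMM on all respondents (species
#'    fixed factor, crossed picture/respondent random intercepts);
#' 3. the same GLMM refit on the kill-selective subset, whose
#'    back-transformed species effects are the misidentification
#'    probabilities eps_i entering the risk ratio;
#' 4. the attitude-versus-mistake GLMM;
#' 5. Monte Carlo kill-risk ratios phi for the two harmless species
#'    (smooth and grass; the adder is the model, not a mimic).
#'
#' Raw selective-subset called-adder proportions are reported alongside the
#' GLMM-derived (conditional) recognition probabilities, since published
#' summaries do not always say which of the two they print.
#'
#' @param dataset a [survey_dataset()]; must pass [validate_survey()] and
#'   contain all three attitude categories, with a nonempty kill-selective
#'   subset.
#' @param n_draws Monte Carlo draws per species (default 10000).
#' @param seed integer seed for the Monte Carlo (default 20140601).
#' @param marginal report marginal (population-averaged) recognition
#'   probabilities instead of conditional (random effects at zero).
#' @param joint_attitude,scale,continuity_correction passed to
#'   [monte_carlo_risk_ratio()].
#' @param unknown_as_mistake,drop_unknown_for_adder_model response-coding
#'   conventions, see [glmm_spec()].
#' @param control a [glmm_control()].
#' @param verbose log stage progress and dimensions to `message()`.
#' @return object of class `mimicry_analysis_report`.
#' @export
run_analysis <- function(dataset, n_draws = 10000, seed = 20140601,
                         marginal = FALSE, joint_attitude = FALSE,
                         scale = "link", continuity_correction = FALSE,
                         unknown_as_mistake = FALSE,
                         drop_unknown_for_adder_model = FALSE,
                         control = glmm_control(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  viol <- validate_survey(dataset)
  if (length(viol) > 0) {
    mr_error(paste0("dataset fails validation:\n  - ",
                    paste(viol, collapse = "\n  - ")),
             "mimicryrisk_pipeline_error")
  }
  check_attitudes_complete(dataset)
  n_sel <- sum(dataset$respondents$attitude == "kill_selective")
  if (n_sel == 0) {
    mr_error(paste("no kill-selective respondents: phi is undefined without",
                   "muv-respondents (no selective-killing risk to propagate)"),
             "mimicryrisk_pipeline_error")
  }
  say("stage 1/5: attitude proportions (n = %d respondents)",
      nrow(dataset$respondents))
  att <- attitude_proportions(dataset)

  say("stage 2/5: identification GLMM, all respondents (%d trials)",
      nrow(dataset$trials))
  fit_all <- fit_binomial_glmm(
    dataset,
    glmm_spec("called_adder",
              drop_unknown_for_adder_model = drop_unknown_for_adder_model),
    control = control)
  say("  converged: %s (var_pic %.3f, var_resp %.3f)", fit_all$converged,
      fit_all$var_picture, fit_all$var_respondent)

  say("stage 3/5: identification GLMM, kill-selective subset (%d respondents)",
      n_sel)
  fit_sel <- fit_binomial_glmm(
    dataset,
    glmm_spec("called_adder", subset_attitude = "kill_selective",
              drop_unknown_for_adder_model = drop_unknown_for_adder_model),
    control = control)

  say("stage 4/5: attitude-vs-mistake GLMM")
  fit_mis <- fit_mistake_model(dataset,
                               unknown_as_mistake = unknown_as_mistake,
                               control = control)

  ptype <- if (marginal) "marginal" else "conditional"
  rec_all <- lapply(species_levels(), function(sp)
    population_probability(fit_all, sp, type = ptype))
  names(rec_all) <- species_levels()
  rec_sel <- lapply(species_levels(), function(sp)
    population_probability(fit_sel, sp, type = ptype))
  names(rec_sel) <- species_levels()

  raw_sel <- raw_called_adder_proportions(
    dataset, subset_attitude = "kill_selective",
    drop_unknown = drop_unknown_for_adder_model)

  # eps enters the risk ratio on the link scale with the fixed-effect SE
  eps <- lapply(rec_sel, function(r) list(eta = r$eta, se_eta = r$se_eta))
  inputs <- kill_risk_inputs(mu0 = att$kill_all, muv = att$kill_selective,
                             eps = eps[c("smooth", "grass")])

  say("stage 5/5: Monte Carlo risk ratios (%d draws, seed %d)", n_draws, seed)
  phi <- lapply(c(smooth = "smooth", grass = "grass"), function(sp)
    monte_carlo_risk_ratio(inputs, sp, n_draws = n_draws, seed = seed,
                           scale = scale, joint_attitude = joint_attitude,
                           continuity_correction = continuity_correction))
  phi_delta <- lapply(c(smooth = "smooth", grass = "grass"), function(sp)
    delta_method_risk_ratio(inputs, sp,
                            continuity_correction = continuity_correction))

  wald <- wald_contrasts(fit_all)

  structure(list(
    attitude_estimates = att,
    identification_fit_all = fit_all,
    identification_fit_selective = fit_sel,
    mistake_fit = fit_mis,
    recognition_probs_all = rec_all,
    recognition_probs_selective = rec_sel,
    raw_subset_proportions = raw_sel,
    species_contrasts = wald,
    phi = phi,
    phi_delta_method = phi_delta,
    provenance = list(
      package_version = as.character(packageVersion("mimicryrisk")),
      seed = as.integer(seed), n_draws = as.integer(n_draws),
      n_respondents = nrow(dataset$respondents),
      n_trials = nrow(dataset$trials),
      options = list(marginal = marginal, joint_attitude = joint_attitude,
                     scale = scale,
                     continuity_correction = continuity_correction,
                     unknown_as_mistake = unknown_as_mistake,
                     drop_unknown_for_adder_model = drop_unknown_for_adder_model))),
    class = "mimicry_analysis_report")
}

# Raw per-species called-adder proportions in a respondent subset.
raw_called_adder_proportions <- function(dataset, subset_attitude = NULL,
                                         drop_unknown = FALSE) {
  t <- dataset$trials
  if (!is.null(subset_attitude)) {
    r <- dataset$respondents
    keep <- r$respondent_id[r$attitude %in% subset_attitude]
    t <- t[t$respondent_id %in% keep, , drop = FALSE]
  }
  if (drop_unknown) t <- t[t$response != "unknown", , drop = FALSE]
  out <- lapply(species_levels(), function(sp) {
    tt <- t[t$true_species == sp, , drop = FALSE]
    fit_intercept_glm(sum(tt$response == "adder"), nrow(tt))
  })
  setNames(out, species_levels())
}

# Wald z-tests of the non-reference species contrasts against the adder.
wald_contrasts <- function(fit) {
  se <- sqrt(diag(fit$vcov_beta))
  out <- lapply(seq_along(fit$beta)[-1], function(i) {
    z <- fit$beta[[i]] / se[[i]]
    list(level = fit$levels[i], estimate = fit$beta[[i]], se = se[[i]],
         z = z, p_value = 2 * stats::pnorm(-abs(z)),
         significant_at_0.05 = abs(z) > qnorm(0.975))
  })
  setNames(out, fit$levels[-1])
}

#' @export
print.mimicry_analysis_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

format_report_text <- function(report) {
  att <- report$attitude_estimates
  rec <- report$recognition_probs_selective
  raw <- report$raw_subset_proportions
  lines <- c(
    "Mimicry kill-risk analysis",
    sprintf("  respondents: %d, trials: %d",
            report$provenance$n_respondents, report$provenance$n_trials),
    "",
    "Attitudes toward killing snakes:",
    sprintf("  no_kill        %5.1f%%  (%d/%d)",
            100 * att$no_kill$p_hat, att$no_kill$k, att$no_kill$n),
    sprintf("  kill_all       %5.1f%%  (%d/%d)  -> mu0",
            100 * att$kill_all$p_hat, att$kill_all$k, att$kill_all$n),
    sprintf("  kill_selective %5.1f%%  (%d/%d)  -> muv",
            100 * att$kill_selective$p_hat, att$kill_selective$k,
            att$kill_selective$n),
    "",
    "Identified-as-adder probability, kill-selective subset:",
    sprintf("  %-7s GLMM %.3f [%.3f, %.3f]   raw %.3f (%d/%d)",
            names(rec), vapply(rec, `[[`, 0, "prob"),
            vapply(rec, `[[`, 0, "ci_low"), vapply(rec, `[[`, 0, "ci_high"),
            vapply(raw, `[[`, 0, "p_hat"),
            vapply(raw, function(r) r$k, 0L),
            vapply(raw, function(r) r$n, 0L)),
    "",
    sprintf("Identification GLMM (all respondents): var(picture) = %.3f, var(respondent) = %.3f",
            report$identification_fit_all$var_picture,
            report$identification_fit_all$var_respondent),
    "",
    "Kill-risk ratios (Monte Carlo, percentile 95% CI):")
  for (sp in names(report$phi)) {
    p <- report$phi[[sp]]
    lines <- c(lines, sprintf(
      "  phi[%-6s] = %.3f  CI [%.3f, %.3f]  (mean %.3f, plug-in %.3f, %d draws)",
      sp, p$phi_median, p$ci_low, p$ci_high, p$phi_mean, p$phi_plugin,
      p$n_draws))
  }
  lines
}

proportion_as_list <- function(e) {
  list(k = e$k, n = e$n, p_hat = e$p_hat, eta_hat = e$eta_hat,
       se_eta = e$se_eta, ci_low = e$ci_low, ci_high = e$ci_high,
       boundary = e$boundary)
}

glmm_fit_as_list <- function(fit) {
  list(response = fit$spec$response, fixed_factor = fit$spec$fixed_factor,
       subset_attitude = fit$spec$subset_attitude,
       levels = fit$levels,
       beta = as.list(fit$beta),
       vcov_beta = unname(lapply(seq_len(nrow(fit$vcov_beta)),
                                 function(i) as.list(unname(fit$vcov_beta[i, ])))),
       var_picture = fit$var_picture, var_respondent = fit$var_respondent,
       loglik = fit$loglik, converged = fit$converged,
       boundary_flags = as.list(fit$boundary_flags),
       n_obs = fit$n_obs, n_pictures = fit$n_pictures,
       n_respondents = fit$n_respondents)
}

report_as_list <- function(report) {
  list(
    attitude_estimates = lapply(unclass(report$attitude_estimates),
                                proportion_as_list),
    identification_fit_all = glmm_fit_as_list(report$identification_fit_all),
    identification_fit_selective =
      glmm_fit_as_list(report$identification_fit_selective),
    mistake_fit = glmm_fit_as_list(report$mistake_fit),
    recognition_probs_all = report$recognition_probs_all,
    recognition_probs_selective = report$recognition_probs_selective,
    raw_subset_proportions = lapply(report$raw_subset_proportions,
                                    proportion_as_list),
    species_contrasts = report$species_contrasts,
    phi = lapply(report$phi, function(p)
      p[c("species", "phi_plugin", "phi_median", "phi_mean", "ci_low",
          "ci_high", "n_draws", "seed", "scale", "joint_attitude", "inputs")]),
    phi_delta_method = report$phi_delta_method,
    provenance = report$provenance)
}

#' Write an analysis report
#'
#' `"json"` writes a lossless single-file serialization (full precision,
#' no timestamps, so identical analyses produce byte-identical files).
#' `"csv_bundle"` writes one CSV per report block into a directory.
#' `"text"` writes the human-readable summary, one line per species for
#' the risk ratios.
#'
#' @param report a [run_analysis()] result.
#' @param path output file (json/text) or directory (csv_bundle).
#' @param format `"json"`, `"csv_bundle"` or `"text"`.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("json", "csv_bundle", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "mimicry_analysis_report"))
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  } else if (format == "text") {
    writeLines(format_report_text(report), path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    att <- report$attitude_estimates
    write.csv(data.frame(
      attitude = names(att),
      k = vapply(att, function(e) e$k, 0L),
      n = vapply(att, function(e) e$n, 0L),
      p_hat = vapply(att, `[[`, 0, "p_hat"),
      eta_hat = vapply(att, `[[`, 0, "eta_hat"),
      se_eta = vapply(att, `[[`, 0, "se_eta"),
      ci_low = vapply(att, `[[`, 0, "ci_low"),
      ci_high = vapply(att, `[[`, 0, "ci_high")),
      file.path(path, "attitudes.csv"), row.names = FALSE)
    rec <- function(lst) data.frame(
      species = names(lst),
      prob = vapply(lst, `[[`, 0, "prob"),
      eta = vapply(lst, `[[`, 0, "eta"),
      se_eta = vapply(lst, `[[`, 0, "se_eta"),
      ci_low = vapply(lst, `[[`, 0, "ci_low"),
      ci_high = vapply(lst, `[[`, 0, "ci_high"))
    write.csv(cbind(fit = "all", rec(report$recognition_probs_all)),
              file.path(path, "recognition_all.csv"), row.names = FALSE)
    write.csv(cbind(fit = "kill_selective",
                    rec(report$recognition_probs_selective)),
              file.path(path, "recognition_selective.csv"), row.names = FALSE)
    fits <- list(all = report$identification_fit_all,
                 selective = report$identification_fit_selective,
                 mistake = report$mistake_fit)
    write.csv(data.frame(
      fit = names(fits),
      var_picture = vapply(fits, `[[`, 0, "var_picture"),
      var_respondent = vapply(fits, `[[`, 0, "var_respondent"),
      loglik = vapply(fits, `[[`, 0, "loglik"),
      converged = vapply(fits, `[[`, TRUE, "converged"),
      n_obs = vapply(fits, `[[`, 0L, "n_obs")),
      file.path(path, "variance_components.csv"), row.names = FALSE)
    phi <- report$phi
    write.csv(data.frame(
      species = names(phi),
      phi_median = vapply(phi, `[[`, 0, "phi_median"),
      phi_mean = vapply(phi, `[[`, 0, "phi_mean"),
      phi_plugin = vapply(phi, `[[`, 0, "phi_plugin"),
      ci_low = vapply(phi, `[[`, 0, "ci_low"),
      ci_high = vapply(phi, `[[`, 0, "ci_high"),
      n_draws = vapply(phi, function(p) p$n_draws, 0L),
      seed = vapply(phi, function(p) p$seed, 0L)),
      file.path(path, "risk_ratios.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' Reconstructs the numeric content of a report written by
#' [write_report()] with `format = "json"`. Round-trips exactly.
#'
#' @param path JSON file path.
#' @return a nested list mirroring the report blocks.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
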