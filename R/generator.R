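#' Configuration for the synthetic survey generator
#'
#' Ground-truth parameters for simulating an identification survey with the
#' statistical structure the analysis assumes. Defaults mirror the scale and
#' published summaries of the field study the pipeline replicates: 102
#' respondents, attitude split 69.6% / 9.8% / 20.6%
#' (no-kill / kill-all / kill-selective), nine pictures (three per species),
#' smooth snakes called "adder" 67.7% of the time and grass snakes 7.2%
#' (selective killers, average picture and respondent), and random-intercept
#' variances 0.134 (picture) and 1.128 (respondent).
#'
#' @param n_respondents number of respondents.
#' @param pi_no_kill,pi_kill_all,pi_kill_selective attitude probabilities;
#'   must sum to 1.
#' @param beta_adder,beta_smooth,beta_grass logit-scale intercepts for the
#'   probability that a picture of that species is called "adder" by a
#'   kill-selective respondent of average skill, for an average picture.
#' @param delta_attitude named logit offsets added to the call-adder linear
#'   predictor by attitude (reference `kill_selective` = 0). The default
#'   +0.8 for `no_kill` and `kill_all` makes non-selective respondents less
#'   accurate, matching the observed direction of the attitude-skill
#'   association.
#' @param sigma_picture,sigma_respondent SDs of the picture and respondent
#'   random intercepts (>= 0).
#' @param p_unknown probability that an answer which is not "adder" is
#'   recorded as `"unknown"`.
#' @param p_cross_confusion probability that a non-adder, non-unknown
#'   answer names the wrong harmless species.
#' @param p_saw_snake probability a respondent saw a snake in the last year.
#' @param n_pictures_per_species pictures per species (default 3).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_respondents = 102,
                             pi_no_kill = 0.696,
                             pi_kill_all = 0.098,
                             pi_kill_selective = 0.206,
                             beta_adder = qlogis(0.75),
                             beta_smooth = qlogis(0.677),
                             beta_grass = qlogis(0.072),
                             delta_attitude = c(no_kill = 0.8, kill_all = 0.8,
                                                kill_selective = 0),
                             sigma_picture = sqrt(0.134),
                             sigma_respondent = sqrt(1.128),
                             p_unknown = 0.10,
                             p_cross_confusion = 0.15,
                             p_saw_snake = 0.94,
                             n_pictures_per_species = 3,
                             seed = 1L) {
  cfg <- structure(list(
    n_respondents = as.integer(n_respondents),
    pi_no_kill = pi_no_kill, pi_kill_all = pi_kill_all,
    pi_kill_selective = pi_kill_selective,
    beta_adder = beta_adder, beta_smooth = beta_smooth,
    beta_grass = beta_grass,
    delta_attitude = delta_attitude,
    sigma_picture = sigma_picture, sigma_respondent = sigma_respondent,
    p_unknown = p_unknown, p_cross_confusion = p_cross_confusion,
    p_saw_snake = p_saw_snake,
    n_pictures_per_species = as.integer(n_pictures_per_species),
    seed = as.integer(seed)), class = "generator_config")
  check_generator_config(cfg)
  cfg
}

check_generator_config <- function(cfg) {
  bad <- function(field, msg) {
    mr_error(sprintf("invalid generator config field '%s': %s", field, msg),
             "mimicryrisk_config_error")
  }
  if (cfg$n_respondents < 1) bad("n_respondents", "must be >= 1")
  pis <- c(cfg$pi_no_kill, cfg$pi_kill_all, cfg$pi_kill_selective)
  if (any(pis < 0)) bad("pi_*", "attitude probabilities must be >= 0")
  if (abs(sum(pis) - 1) > 1e-12) bad("pi_*", "attitude probabilities must sum to 1")
  if (cfg$sigma_picture < 0) bad("sigma_picture", "must be >= 0")
  if (cfg$sigma_respondent < 0) bad("sigma_respondent", "must be >= 0")
  for (f in c("p_unknown", "p_cross_confusion", "p_saw_snake")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must be in [0, 1]")
  }
  need <- setdiff(attitude_levels(), names(cfg$delta_attitude))
  if (length(need) > 0) {
    bad("delta_attitude", paste("missing offsets for", paste(need, collapse = ", ")))
  }
  if (cfg$n_pictures_per_species < 1) bad("n_pictures_per_species", "must be >= 1")
  invisible(cfg)
}

# Run `expr` under the given seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic identification survey
#'
#' Simulates a survey from known ground truth, so the full pipeline can be
#' tested end to end and parameter recovery can be checked against the
#' generating values. Deterministic given `config$seed`.
#'
#' Procedure: attitudes are drawn from the categorical distribution
#' `(pi_no_kill, pi_kill_all, pi_kill_selective)`; picture intercepts
#' `a_j ~ N(0, sigma_picture^2)` and respondent intercepts
#' `b_i ~ N(0, sigma_respondent^2)` are drawn once; each respondent x
#' picture trial is called "adder" with probability
#' `plogis(beta_species + delta_attitude + a_j + b_i)`. A trial not called
#' adder is `"unknown"` with probability `p_unknown`; otherwise it names
#' the correct species with probability `1 - p_cross_confusion` and the
#' remaining harmless species otherwise (for adder pictures the two
#' harmless labels are used with equal probability). Sightings are drawn
#' independently of attitude.
#'
#' @param config a [generator_config()].
#' @return a validated [survey_dataset()].
#' @export
generate_survey <- function(config = generator_config()) {
  check_generator_config(config)
  with_local_seed(config$seed, generate_survey_impl(config))
}

generate_survey_impl <- function(cfg) {
  n <- cfg$n_respondents
  ids <- sprintf("R%04d", seq_len(n))
  att <- sample(attitude_levels(), n, replace = TRUE,
                prob = c(cfg$pi_no_kill, cfg$pi_kill_all, cfg$pi_kill_selective))
  saw <- runif(n) < cfg$p_saw_snake
  where <- ifelse(saw,
                  sample(c("yard", "nature", "both"), n, replace = TRUE,
                         prob = c(0.25, 0.55, 0.20)),
                  "none")
  municipality <- sample(c("Mariehamn", "Jomala", "Hammarland", "Sund", "Lemland"),
                         n, replace = TRUE)
  respondents <- data.frame(
    respondent_id = ids, municipality = municipality,
    saw_snake_last_year = saw, seen_where = where, attitude = att,
    stringsAsFactors = FALSE)

  npp <- cfg$n_pictures_per_species
  pic_species <- rep(species_levels(), each = npp)
  pic_ids <- paste0(pic_species, "_", rep(seq_len(npp), times = 3))
  a_pic <- rnorm(length(pic_ids), 0, cfg$sigma_picture)
  b_resp <- rnorm(n, 0, cfg$sigma_respondent)
  beta <- c(adder = cfg$beta_adder, smooth = cfg$beta_smooth,
            grass = cfg$beta_grass)
  delta <- cfg$delta_attitude[att]  # per respondent

  # long layout: respondent index varies slowest
  ri <- rep(seq_len(n), each = length(pic_ids))
  pj <- rep(seq_along(pic_ids), times = n)
  eta <- beta[pic_species[pj]] + delta[ri] + a_pic[pj] + b_resp[ri]
  called_adder <- runif(length(eta)) < plogis(eta)

  response <- character(length(eta))
  response[called_adder] <- "adder"
  idx <- which(!called_adder)
  if (length(idx) > 0) {
    unk <- runif(length(idx)) < cfg$p_unknown
    response[idx[unk]] <- "unknown"
    rest <- idx[!unk]
    if (length(rest) > 0) {
      sp <- pic_species[pj[rest]]
      cross <- runif(length(rest)) < cfg$p_cross_confusion
      harmless <- c(smooth = "grass", grass = "smooth")
      out <- ifelse(cross, harmless[sp], sp)
      # adder pictures not called adder: split harmless labels evenly
      is_adder <- sp == "adder"
      if (any(is_adder)) {
        out[is_adder] <- sample(c("smooth", "grass"), sum(is_adder),
                                replace = TRUE)
      }
      response[rest] <- out
    }
  }

  trials <- data.frame(
    respondent_id = ids[ri], picture_id = pic_ids[pj],
    true_species = pic_species[pj], response = response,
    stringsAsFactors = FALSE)
  survey_dataset(respondents, trials, check = FALSE)
}

#' Generate an ensemble of independent synthetic surveys
#'
#' Replicate `r` uses seed `base_seed + r`, so ensembles are reproducible
#' and replicates mutually independent.
#'
#' @param config a [generator_config()]; its `seed` field is overridden.
#' @param n_replicates number of surveys (>= 1).
#' @param base_seed integer; replicate r gets seed `base_seed + r`.
#' @return list of [survey_dataset()] objects.
#' @export
generate_survey_ensemble <- function(config, n_replicates, base_seed) {
  if (n_replicates < 1) {
    mr_error("n_replicates must be >= 1", "mimicryrisk_config_error")
  }
  lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    generate_survey(cfg)
  })
}

#' Ground-truth parameter list for a generator configuration
#'
#' Collects the generating values a recovery study compares against,
#' including the analytic kill-risk ratios implied by the configuration
#' (conditional scale, random effects at zero):
#' `phi_i = 1 + pi_kill_selective * plogis(beta_i) / pi_kill_all`.
#'
#' @param config a [generator_config()].
#' @return list of true parameters, suitable for `truth.json`.
#' @export
generator_truth <- function(config) {
  eps <- c(smooth = plogis(config$beta_smooth),
           grass = plogis(config$beta_grass))
  phi <- 1 + config$pi_kill_selective * eps / config$pi_kill_all
  list(
    n_respondents = config$n_respondents,
    pi = c(no_kill = config$pi_no_kill, kill_all = config$pi_kill_all,
           kill_selective = config$pi_kill_selective),
    call_adder_prob = c(adder = plogis(config$beta_adder),
                        smooth = plogis(config$beta_smooth),
                        grass = plogis(config$beta_grass)),
    beta = c(adder = config$beta_adder, smooth = config$beta_smooth,
             grass = config$beta_grass),
    delta_attitude = as.list(config$delta_attitude),
    var_picture = config$sigma_picture^2,
    var_respondent = config$sigma_respondent^2,
    p_unknown = config$p_unknown,
    p_cross_confusion = config$p_cross_confusion,
    p_saw_snake = config$p_saw_snake,
    phi = as.list(phi),
    seed = config$seed)
}

#' Read or write a generator configuration as JSON
#'
#' Flat key-value JSON mirroring the [generator_config()] fields
#' (`delta_attitude` as a nested object).
#'
#' @param path JSON file path.
#' @param config a [generator_config()].
#' @return `read_generator_config` returns a `generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$delta_attitude)) {
    vals$delta_attitude <- unlist(vals$delta_attitude)
  }
  do.call(generator_config, vals)
}

#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  obj <- unclass(config)
  obj$delta_attitude <- as.list(obj$delta_attitude)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
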