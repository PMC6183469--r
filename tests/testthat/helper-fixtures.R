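# Tiny hand-built survey: 2 respondents x 9 pictures.
tiny_survey <- function() {
  pics <- paste0(rep(c("adder", "smooth", "grass"), each = 3), "_", 1:3)
  sp <- rep(c("adder", "smooth", "grass"), each = 3)
  respondents <- data.frame(
    respondent_id = c("R1", "R2"),
    municipality = c("Jomala", "Sund"),
    saw_snake_last_year = c(TRUE, FALSE),
    seen_where = c("yard", "none"),
    attitude = c("kill_selective", "no_kill"),
    stringsAsFactors = FALSE)
  trials <- data.frame(
    respondent_id = rep(c("R1", "R2"), each = 9),
    picture_id = rep(pics, 2),
    true_species = rep(sp, 2),
    response = c("adder", "adder", "adder", "adder", "smooth", "unknown",
                 "grass", "grass", "smooth",
                 "adder", "unknown", "smooth", "smooth", "adder", "smooth",
                 "grass", "unknown", "grass"),
    stringsAsFactors = FALSE)
  list(respondents = respondents, trials = trials)
}

tiny_dataset <- function() {
  f <- tiny_survey()
  survey_dataset(f$respondents, f$trials)
}

# fast generator config for unit tests
quick_config <- function(...) {
  generator_config(n_respondents = 60, seed = 42, ...)
}
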