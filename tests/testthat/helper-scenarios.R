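# programmatic scenarios for tests: full 21-parameter coverage built in code

lognormal_indices <- function() c(13L, 15:18)

# one marginal spec per parameter, same location/spread rules per arm.
# `spread` is the q3/median (and median/q1) ratio for lognormal parameters.
make_scenario <- function(healthy = (1:21) * 10, baseline = (1:21) * 10,
                          month6 = (1:21) * 10, sds = rep(1, 21),
                          corr = NULL, gender = NULL,
                          n_diabetic = 40, n_healthy = 27,
                          fraction_female = 0.5, within_patient_r = 0.8,
                          spread = 1.5) {
  marg <- lapply(1:21, function(i) {
    mk <- function(m, s) {
      if (i %in% lognormal_indices()) {
        if (s == 0) list(median = m, q1 = m, q3 = m)
        else list(median = m, q1 = m / spread, q3 = m * spread)
      } else {
        list(mean = m, sd = s)
      }
    }
    list(index = i, healthy = mk(healthy[i], sds[i]),
         baseline = mk(baseline[i], sds[i]), month6 = mk(month6[i], sds[i]))
  }
  )
  as_cohort_scenario(list(
    name = "test", marginals = marg, correlations = corr,
    gender_effects = gender, n_diabetic = n_diabetic, n_healthy = n_healthy,
    fraction_female = fraction_female, within_patient_r = within_patient_r))
}

# all arms identical except a strong treatment shift on w19
make_signal_scenario <- function(shift_sd = 10, ...) {
  m6 <- (1:21) * 10
  m6[19] <- m6[19] + shift_sd * 1 # sds are 1
  make_scenario(month6 = m6, ...)
}

# a tiny literal cohort: n_d diabetic pairs + n_h healthy, constant values
tiny_cohort_data <- function(n_d = 2, n_h = 1, value = 1) {
  rows <- list()
  for (i in seq_len(n_h)) {
    r <- data.frame(patient_id = sprintf("H%02d", i), group = "healthy",
                    gender = "F", timepoint = "single", stringsAsFactors = FALSE)
    r[paste0("w", 1:21)] <- as.list(rep(value, 21))
    rows[[length(rows) + 1]] <- r
  }
  for (i in seq_len(n_d)) {
    for (tp in c("baseline", "month6")) {
      r <- data.frame(patient_id = sprintf("D%02d", i), group = "diabetic",
                      gender = if (i %% 2) "F" else "M", timepoint = tp,
                      stringsAsFactors = FALSE)
      r[paste0("w", 1:21)] <- as.list(rep(value, 21) + (tp == "month6") * 0.5)
      rows[[length(rows) + 1]] <- r
    }
  }
  if (!length(rows)) {
    r <- data.frame(patient_id = character(), group = character(),
                    gender = character(), timepoint = character(),
                    stringsAsFactors = FALSE)
    r[paste0("w", 1:21)] <- replicate(21, numeric(), simplify = FALSE)
    return(r)
  }
  do.call(rbind, rows)
}
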