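# Shared fixtures: compact cohort specs built in code, plus a naive
# Mahalanobis oracle kept deliberately independent of the package's
# linear-algebra path (explicit loops, analytic 1x1/2x2 inverses).

# A small spec with a handful of variables for fast pipeline-level tests.
small_spec <- function(n_control = 12, n_patient = 18) {
  cohort_spec(
    n_control = n_control, n_patient = n_patient,
    control_sex = c(F = ceiling(n_control / 2), M = floor(n_control / 2)),
    patient_sex = c(F = ceiling(n_patient / 2), M = floor(n_patient / 2)),
    variables = list(
      normal3_spec("age", 56, 5, 59, 7, 59.6, 7),
      normal3_spec("bmi", 29.6, 6.2, 32.8, 4.8, 32.1, 5.1),
      normal3_spec("whr", 0.95, 0.07, 0.98, 0.06, 0.97, 0.06),
      normal3_spec("glucose", 90.5, 5.1, 113.9, 12.1, 114.2, 14.4),
      normal3_spec("hba1c", 5.2, 0.4, 6.3, 0.6, 6.3, 0.8),
      lognormal3_spec("tg", 162, 50, 177, 93, 142, 66),
      normal3_spec("tc", 181, 27, 197, 45, 182, 29),
      normal3_spec("hdl", 46.8, 8.5, 50.1, 14.8, 51.6, 14.6),
      normal3_spec("ldl", 116, 28, 114, 36, 99, 27),
      normal3_spec("scr", 0.85, 0.10, 0.79, 0.13, 0.85, 0.17),
      lognormal3_spec("ucr", 110, 65, 101, 57, 106, 53),
      lognormal3_spec("ualb", 4.7, 3.8, 6.0, 5.3, 6.1, 5.7),
      lognormal3_spec("insulin", 13.2, 9.7, 10.5, 6.4, 9.5, 5.1),
      lognormal3_spec("homa_ir", 1.16, 0.73, 1.46, 0.83, 1.29, 0.68),
      lognormal3_spec("homa_b", 136, 59, 78, 38, 69, 33),
      normal3_spec("sbp", 122, 7, 136, 11, 132, 11),
      normal3_spec("dbp", 81, 3.4, 82, 5.1, 78, 7.4),
      lognormal_iqr_spec("adropin", c(0.75, 0.62, 1.06), c(0.86, 0.61, 1.07), c(0.74, 0.52, 0.93)),
      lognormal_iqr_spec("irisin", c(4.99, 3.29, 6.16), c(8.83, 5.63, 12.39), c(15.28, 11.39, 19.78)),
      lognormal_iqr_spec("vaspin", c(0.35, 0.21, 0.99), c(0.12, 0.07, 0.29), c(0.29, 0.17, 0.66))
    )
  )
}

normal3_spec <- function(name, c_m, c_s, b_m, b_s, m_m, m_s) {
  variable_spec(name, "normal",
    control = list(mean = c_m, sd = c_s),
    baseline = list(mean = b_m, sd = b_s),
    month6 = list(mean = m_m, sd = m_s)
  )
}

lognormal3_spec <- function(name, c_m, c_s, b_m, b_s, m_m, m_s) {
  variable_spec(name, "lognormal",
    control = list(mean = c_m, sd = c_s),
    baseline = list(mean = b_m, sd = b_s),
    month6 = list(mean = m_m, sd = m_s)
  )
}

lognormal_iqr_spec <- function(name, ctrl, base, m6) {
  as_iqr <- function(v) list(median = v[1], q1 = v[2], q3 = v[3])
  variable_spec(name, "lognormal",
    control = as_iqr(ctrl), baseline = as_iqr(base), month6 = as_iqr(m6)
  )
}

# Patients-only spec whose pre/post separation lives entirely in the named
# signal variables (mean shift `delta` SDs between visits); every other
# variable is identically distributed at both visits.
signal_spec <- function(n_patient = 60, n_signal = 2, n_noise = 4,
                        delta = 2.5, pairing = 0.5) {
  mk <- function(name, shift) {
    variable_spec(name, "normal",
      control = list(mean = 10, sd = 1),
      baseline = list(mean = 10, sd = 1),
      month6 = list(mean = 10 + shift, sd = 1)
    )
  }
  vars <- c(
    lapply(seq_len(n_signal), function(i) mk(paste0("sig", i), delta)),
    lapply(seq_len(n_noise), function(i) mk(paste0("noise", i), 0))
  )
  # age/bmi/whr are schema-required; keep them as inert noise too
  vars <- c(vars, list(
    mk("age", 0), mk("bmi", 0), mk("whr", 0), mk("glucose", 0),
    mk("hba1c", 0), mk("tc", 0), mk("hdl", 0), mk("ldl", 0),
    mk("tg", 0), mk("scr", 0), mk("ucr", 0), mk("ualb", 0),
    mk("insulin", 0), mk("sbp", 0), mk("dbp", 0),
    mk("adropin", 0), mk("irisin", 0), mk("vaspin", 0),
    mk("homa_ir", 0), mk("homa_b", 0)
  ))
  cohort_spec(
    n_control = 4, n_patient = n_patient,
    control_sex = c(F = 2, M = 2),
    patient_sex = c(
      F = ceiling(n_patient / 2),
      M = floor(n_patient / 2)
    ),
    variables = vars, pairing = pairing
  )
}

# Balanced pure-noise pre/post cohort for null-calibration experiments.
noise_spec <- function(n_patient = 24, n_noise = 3) {
  signal_spec(
    n_patient = n_patient, n_signal = 0, n_noise = n_noise,
    delta = 0, pairing = 0
  )
}

# Oracle: two-class Mahalanobis classification by direct evaluation -
# means, pooled covariance and the quadratic form all by explicit loops,
# and the covariance inverse by the analytic 1x1 / 2x2 formula.
oracle_classify <- function(x_learn, y_learn, x_test) {
  classes <- unique(y_learn)
  p <- ncol(x_learn)
  means <- list()
  for (cl in classes) {
    rows <- which(y_learn == cl)
    mu <- numeric(p)
    for (j in seq_len(p)) {
      s <- 0
      for (i in rows) s <- s + x_learn[i, j]
      mu[j] <- s / length(rows)
    }
    means[[cl]] <- mu
  }
  S <- matrix(0, p, p)
  for (cl in classes) {
    rows <- which(y_learn == cl)
    mu <- means[[cl]]
    for (i in rows) {
      for (j in seq_len(p)) {
        for (k in seq_len(p)) {
          S[j, k] <- S[j, k] + (x_learn[i, j] - mu[j]) * (x_learn[i, k] - mu[k])
        }
      }
    }
  }
  S <- S / (nrow(x_learn) - 2)
  if (p == 1) {
    S_inv <- matrix(1 / S[1, 1], 1, 1)
  } else if (p == 2) {
    det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    S_inv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det
  } else {
    stop("oracle supports p <= 2")
  }
  quad <- function(v) {
    q <- 0
    for (j in seq_len(p)) {
      for (k in seq_len(p)) q <- q + v[j] * S_inv[j, k] * v[k]
    }
    q
  }
  apply(x_test, 1, function(row) {
    d <- vapply(classes, function(cl) quad(row - means[[cl]]), numeric(1))
    classes[which(d <= min(d))[1]]
  })
}
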