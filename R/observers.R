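## Synthetic matching-experiment cohorts.  The generative model mirrors
## the paired design of the online experiment: 85 participants, each
## display's left and right target matched four times, responses recorded
## as 8-bit gray values.  A participant's illusion is an additive effect
## delta_p ~ Normal(Md, sigma_p) split evenly between the two sides;
## repetition noise is Normal(0, sigma_r).  The variance split is chosen
## so that the sd of participant-mean differences equals the target SDd:
## sigma_p^2 + 2 sigma_r^2 / reps = SDd^2.

#' Specify a synthetic observer cohort for one display
#'
#' By default the cohort parameters are derived from the embedded human
#' statistics ([table1_stats()]): the true mean difference is the human
#' `Md`, the sd of participant-mean differences is the human `SDd`, the
#' baseline lightness is the veridical target value (0.5, or 0.25/0.75
#' for the dark/light SLC variants), and n = 85 participants x 4
#' repetitions.  `prop_between` sets the (unknowable from the printed
#' table) share of `SDd^2` attributed to between-participant variance;
#' the remainder becomes repetition noise.
#'
#' @param display display identifier with a row in [table1_stats()], or
#'   any name when `Md` and `SDd` are given explicitly.
#' @param Md,SDd true mean and sd of participant-mean differences.
#' @param mu baseline unit lightness of the two targets.
#' @param n participants; `reps` repetitions per side.
#' @param prop_between share of `SDd^2` between participants (default 0.8).
#' @param sigma_p,sigma_r explicit components; when both are supplied they
#'   must satisfy `sigma_p^2 + 2 sigma_r^2 / reps = SDd^2` to 1e-9.
#' @return object of class `observer_model`.
#' @export
#' @examples
#' observer_model("slc")
observer_model <- function(display, Md = NULL, SDd = NULL, mu = NULL,
                           n = 85, reps = 4, prop_between = 0.8,
                           sigma_p = NULL, sigma_r = NULL) {
  t1 <- table1_stats()
  row <- match(display, t1$display)
  if (is.null(Md)) {
    if (is.na(row)) stop("no embedded statistics for '", display,
                         "'; supply Md and SDd")
    Md <- t1$Md[row]
  }
  if (is.null(SDd)) {
    if (is.na(row)) stop("no embedded statistics for '", display,
                         "'; supply Md and SDd")
    SDd <- t1$SDd[row]
  }
  if (is.null(mu)) {
    mu <- switch(display, slc_dark = 0.25, slc_light = 0.75, 0.5)
  }
  stopifnot(SDd >= 0, n >= 2, reps >= 1, mu >= 0, mu <= 1)
  if (is.null(sigma_p) != is.null(sigma_r)) {
    stop("supply both sigma_p and sigma_r, or neither")
  }
  if (is.null(sigma_p)) {
    sigma_p <- sqrt(prop_between) * SDd
    sigma_r <- sqrt((1 - prop_between) * reps / 2) * SDd
  } else {
    implied <- sqrt(sigma_p^2 + 2 * sigma_r^2 / reps)
    if (abs(implied - SDd) > 1e-9) {
      stop("mis-specified model: sigma_p, sigma_r imply sd of ",
           "participant differences ", signif(implied, 6),
           " instead of SDd = ", SDd)
    }
  }
  mu_left <- mu + Md / 2
  mu_right <- mu - Md / 2
  stopifnot(mu_left >= 0, mu_left <= 1, mu_right >= 0, mu_right <= 1)
  structure(list(display = display, Md = Md, SDd = SDd, mu = mu,
                 mu_left = mu_left, mu_right = mu_right,
                 sigma_p = sigma_p, sigma_r = sigma_r,
                 n = as.integer(n), reps = as.integer(reps)),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat("<observer_model> ", x$display, ": Md ", x$Md, ", SDd ", x$SDd,
      ", n ", x$n, " x ", x$reps, " reps, sigma_p ", signif(x$sigma_p, 4),
      ", sigma_r ", signif(x$sigma_r, 4), "\n", sep = "")
  invisible(x)
}

#' Simulate one matching cohort
#'
#' Draws `match(p, side, rep) = mu_side +/- delta_p / 2 + eps` with
#' `delta_p ~ Normal(Md, sigma_p)` and `eps ~ Normal(0, sigma_r)`,
#' truncates to `[0, 1]` and (by default) quantizes to the 8-bit slider
#' resolution.  Fully reproducible from the seed; the caller's RNG state
#' is left untouched.
#'
#' @param model an `observer_model`.
#' @param seed integer seed (required).
#' @param quantize quantize matches to 8-bit gray levels (default TRUE).
#' @return a `match_data` object with `2 * n * reps` rows.
#' @export
#' @examples
#' m <- simulate_matches(observer_model("slc"), seed = 1)
#' nrow(m)
simulate_matches <- function(model, seed, quantize = TRUE) {
  stopifnot(inherits(model, "observer_model"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  with_seed(as.integer(seed), {
    delta <- stats::rnorm(model$n, model$Md, model$sigma_p)
    rows <- expand.grid(repetition = seq_len(model$reps),
                        side = c("left", "right"),
                        participant = seq_len(model$n),
                        stringsAsFactors = FALSE)
    sgn <- ifelse(rows$side == "left", 0.5, -0.5)
    v <- model$mu + sgn * delta[rows$participant] +
      stats::rnorm(nrow(rows), 0, model$sigma_r)
    v <- pmin(pmax(v, 0), 1)
    gray <- if (quantize) round(v * 255) else v * 255
    match_data(data.frame(participant = rows$participant,
                          display = model$display, side = rows$side,
                          repetition = rows$repetition, gray = gray))
  })
}

#' Simulate a null cohort (zero true illusion)
#'
#' As [simulate_matches()] with the true mean difference forced to zero;
#' used for type-I error calibration of the paired test.
#'
#' @inheritParams simulate_matches
#' @export
null_cohort <- function(model, seed, quantize = TRUE) {
  stopifnot(inherits(model, "observer_model"))
  null_model <- model
  null_model$Md <- 0
  null_model$mu_left <- null_model$mu
  null_model$mu_right <- null_model$mu
  simulate_matches(null_model, seed, quantize)
}
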