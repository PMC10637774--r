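#' @section Biolayer interferometry:
#' A sensorgram is a response-vs-time trace over three phases: baseline in
#' buffer, association in analyte, dissociation back in buffer (default
#' schedule 120 s / 180 s / 180 s). Binding follows the 1:1 Langmuir
#' model `dR/dt = kon * C * (Rmax - R) - koff * R`, whose closed form is
#' an exponential approach to `Req = Rmax * C / (C + Kd)` during
#' association (observed rate `kobs = kon * C + koff`) and exponential
#' decay at rate `koff` during dissociation, with `Kd = koff / kon`.
#' Instrument artefacts are handled by four-sensor double referencing:
#' with (a) ligand sensor in analyte, (b) blank sensor in analyte,
#' (c) ligand sensor in buffer, (d) blank sensor in buffer, the
#' referenced signal is `(a - c) - (b - d)`, which cancels any drift
#' common to the sensor pairs and any nonspecific analyte signal seen by
#' the blank sensor.
#' @name bli_kinetics
NULL

#' Assay phase schedule
#'
#' @param baseline,association,dissociation phase durations in seconds.
#' @param dt sampling interval in seconds.
#' @return A `bli_schedule` list.
#' @export
bli_schedule <- function(baseline = 120, association = 180,
                         dissociation = 180, dt = 0.5) {
  stopifnot(baseline >= 0, association > 0, dissociation > 0, dt > 0)
  structure(list(baseline = baseline, association = association,
                 dissociation = dissociation, dt = dt),
            class = "bli_schedule")
}

# Noise/drift-free mechanistic 1:1 response at global times t
langmuir_response <- function(t, kon, koff, Rmax, conc, schedule) {
  t_assoc <- schedule$baseline
  t_diss <- schedule$baseline + schedule$association
  r <- numeric(length(t))
  assoc <- t >= t_assoc & t < t_diss
  if (conc > 0) {
    kobs <- kon * conc + koff
    Req <- if (kobs > 0) Rmax * kon * conc / kobs else 0
    r[assoc] <- Req * (1 - exp(-kobs * (t[assoc] - t_assoc)))
    r_end <- Req * (1 - exp(-kobs * schedule$association))
  } else r_end <- 0
  diss <- t >= t_diss
  r[diss] <- r_end * exp(-koff * (t[diss] - t_diss))
  r
}

#' Simulate a single sensorgram
#'
#' The mechanistic 1:1 Langmuir signal plus an additive linear drift
#' `drift_rate * t` and i.i.d. Gaussian noise.
#'
#' @param kon association rate (1/M/s), `>= 0`.
#' @param koff dissociation rate (1/s), `>= 0`.
#' @param Rmax saturation response (signal units).
#' @param conc analyte concentration (M).
#' @param schedule a [bli_schedule()].
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param drift_rate linear drift slope (signal units / s).
#' @param seed optional integer seed.
#' @param sensor_role one of `"a"`, `"b"`, `"c"`, `"d"`, or
#'   `"referenced"`.
#' @return A `sensorgram` data frame with columns `time_s`, `response`,
#'   `phase`, and attributes `conc_M`, `sensor_role`, `schedule`.
#' @export
simulate_sensorgram <- function(kon, koff, Rmax, conc,
                                schedule = bli_schedule(),
                                noise_sd = 0, drift_rate = 0, seed = NULL,
                                sensor_role = "a") {
  if (kon < 0 || koff < 0 || Rmax < 0 || conc < 0)
    stop("rates, Rmax and concentration must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  total <- schedule$baseline + schedule$association + schedule$dissociation
  t <- seq(0, total, by = schedule$dt)
  r <- langmuir_response(t, kon, koff, Rmax, conc, schedule)
  r <- r + drift_rate * t
  if (noise_sd > 0) r <- r + rnorm(length(t), sd = noise_sd)
  new_sensorgram(t, r, conc, sensor_role, schedule)
}

new_sensorgram <- function(t, r, conc, role, schedule) {
  phase <- ifelse(t < schedule$baseline, "baseline",
                  ifelse(t < schedule$baseline + schedule$association,
                         "association", "dissociation"))
  structure(data.frame(time_s = t, response = r, phase = phase,
                       stringsAsFactors = FALSE),
            conc_M = conc, sensor_role = role, schedule = schedule,
            class = c("sensorgram", "data.frame"))
}

#' Four-sensor double referencing
#'
#' Computes the referenced trace `(a - c) - (b - d)` pointwise, removing
#' sensor drift and nonspecific analyte signal.
#'
#' @param a ligand sensor in analyte.
#' @param b blank sensor in analyte.
#' @param c_ ligand sensor in buffer.
#' @param d blank sensor in buffer.
#' @return A referenced `sensorgram` (phases and concentration inherited
#'   from `a`).
#' @export
double_reference <- function(a, b, c_, d) {
  roles <- c(attr(a, "sensor_role"), attr(b, "sensor_role"),
             attr(c_, "sensor_role"), attr(d, "sensor_role"))
  if (!identical(roles, c("a", "b", "c", "d")))
    stop("sensorgrams must be supplied in roles a, b, c, d; got: ",
         paste(roles, collapse = ", "))
  for (s in list(b, c_, d))
    if (!isTRUE(all.equal(s$time_s, a$time_s)))
      stop("sensorgrams do not share a common time grid")
  new_sensorgram(a$time_s,
                 (a$response - c_$response) - (b$response - d$response),
                 attr(a, "conc_M"), "referenced", attr(a, "schedule"))
}

#' Simulate a full four-sensor plate over a concentration series
#'
#' Per concentration, four sensorgrams sharing one drift realization:
#' role a carries the specific signal plus nonspecific analyte signal,
#' role b only the nonspecific signal, roles c and d only drift and noise.
#' Double referencing therefore recovers the specific signal exactly in
#' the noiseless case.
#'
#' @inheritParams simulate_sensorgram
#' @param concentrations analyte concentrations (M); default 7 two-fold
#'   dilutions bracketing the generating Kd.
#' @param nonspecific_rate slope of the nonspecific analyte signal seen by
#'   both analyte wells during association (signal units / s at 1 M,
#'   scaled by concentration).
#' @param seed integer seed.
#' @return A `bli_plate` list: `wells` (one element per concentration with
#'   sensorgrams `a`, `b`, `c`, `d`), `referenced` (double-referenced
#'   trace per concentration), and the generating parameters.
#' @export
generate_sensorgram_plate <- function(kon, koff, Rmax,
                                      concentrations = NULL,
                                      schedule = bli_schedule(),
                                      noise_sd = 0, drift_rate = 0,
                                      nonspecific_rate = 0, seed = 1L) {
  if (is.null(concentrations)) {
    Kd <- koff / kon
    concentrations <- Kd * 2^seq(-3, 3)
  }
  set.seed(seed)
  total <- schedule$baseline + schedule$association + schedule$dissociation
  t <- seq(0, total, by = schedule$dt)
  assoc <- t >= schedule$baseline & t < schedule$baseline + schedule$association
  wells <- list(); referenced <- list()
  for (ci in seq_along(concentrations)) {
    conc <- concentrations[ci]
    drift <- drift_rate * t
    ns <- numeric(length(t))
    ns[assoc] <- nonspecific_rate * conc * (t[assoc] - schedule$baseline)
    sig <- langmuir_response(t, kon, koff, Rmax, conc, schedule)
    noise <- function() if (noise_sd > 0) rnorm(length(t), sd = noise_sd) else 0
    a <- new_sensorgram(t, sig + ns + drift + noise(), conc, "a", schedule)
    b <- new_sensorgram(t, ns + drift + noise(), conc, "b", schedule)
    c_ <- new_sensorgram(t, drift + noise(), conc, "c", schedule)
    d <- new_sensorgram(t, drift + noise(), conc, "d", schedule)
    wells[[ci]] <- list(a = a, b = b, c = c_, d = d)
    referenced[[ci]] <- double_reference(a, b, c_, d)
  }
  structure(list(wells = wells, referenced = referenced,
                 concentrations = concentrations,
                 params = list(kon = kon, koff = koff, Rmax = Rmax,
                               noise_sd = noise_sd, drift_rate = drift_rate,
                               nonspecific_rate = nonspecific_rate,
                               seed = seed),
                 schedule = schedule),
            class = "bli_plate")
}

# residuals of the global 1:1 model in log10 parameter space, association
# and dissociation phases only
.kinetic_resid <- function(logpar, sensorgrams, concs, schedule) {
  kon <- 10^logpar[1]; koff <- 10^logpar[2]; Rmax <- 10^logpar[3]
  unlist(lapply(seq_along(sensorgrams), function(i) {
    sg <- sensorgrams[[i]]
    sel <- sg$phase != "baseline"
    sg$response[sel] -
      langmuir_response(sg$time_s[sel], kon, koff, Rmax, concs[i], schedule)
  }))
}

#' Global 1:1 kinetic fit of a referenced concentration series
#'
#' Nonlinear least squares (Levenberg-Marquardt, log10 parameter space,
#' bounded) of the 1:1 Langmuir model with kon, koff and Rmax shared
#' across all concentrations. Multi-start: a data-driven start (plateau
#' and dissociation-decay estimates) plus log-spaced grid starts; the best
#' residual sum of squares wins.
#'
#' @param sensorgrams list of referenced `sensorgram` objects over at
#'   least 3 distinct analyte concentrations.
#' @param kon_bounds,koff_bounds parameter bounds (1/M/s and 1/s).
#' @param n_starts number of additional log-spaced starts (>= 4).
#' @return A `kinetic_fit` list: `kon`, `koff`, `Rmax`, `Kd = koff/kon`,
#'   `rss`, `converged`, `n_starts`.
#' @export
fit_kinetics <- function(sensorgrams, kon_bounds = c(1e2, 1e8),
                         koff_bounds = c(1e-6, 1), n_starts = 5L) {
  concs <- vapply(sensorgrams, attr, 0, "conc_M")
  if (length(unique(concs[concs > 0])) < 3)
    stop("global kinetic fitting needs >= 3 distinct analyte concentrations")
  schedule <- attr(sensorgrams[[1]], "schedule")

  # data-driven start: koff from log-linear dissociation decay at the top
  # concentration, Rmax/Kd from the plateau-vs-concentration curve
  top <- which.max(concs)
  sg <- sensorgrams[[top]]
  diss <- sg[sg$phase == "dissociation", ]
  pos <- diss$response > max(diss$response, 1e-12) * 0.05
  koff0 <- if (sum(pos) > 5) {
    sl <- coef(lm(log(diss$response[pos]) ~ diss$time_s[pos]))[2]
    max(min(-sl, koff_bounds[2]), koff_bounds[1])
  } else sqrt(prod(koff_bounds))
  plateaus <- vapply(sensorgrams, function(s) {
    as_ <- s[s$phase == "association", ]
    mean(utils::tail(as_$response, max(3L, nrow(as_) %/% 20L)))
  }, 0)
  Rmax0 <- max(plateaus) * 1.2
  half <- plateaus >= 0.5 * max(plateaus)
  Kd0 <- if (any(half)) min(concs[half]) else stats::median(concs)
  kon0 <- max(min(koff0 / Kd0, kon_bounds[2]), kon_bounds[1])

  lower <- c(log10(kon_bounds[1]), log10(koff_bounds[1]), log10(max(Rmax0, 1)) - 4)
  upper <- c(log10(kon_bounds[2]), log10(koff_bounds[2]), log10(max(Rmax0, 1)) + 4)
  starts <- list(c(log10(kon0), log10(koff0), log10(max(Rmax0, 1e-6))))
  grid_kon <- 10^seq(log10(kon_bounds[1]) + 1, log10(kon_bounds[2]) - 1,
                     length.out = n_starts)
  grid_koff <- 10^seq(log10(koff_bounds[1]) + 1, log10(koff_bounds[2]) - 0.5,
                      length.out = n_starts)
  for (k in seq_len(n_starts))
    starts[[k + 1L]] <- c(log10(grid_kon[k]), log10(grid_koff[k]),
                          log10(max(Rmax0, 1e-6)))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = .kinetic_resid, sensorgrams = sensorgrams,
                         concs = concs, schedule = schedule,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best)) stop("all optimizer starts failed")
  kon <- 10^best$par[1]; koff <- 10^best$par[2]; Rmax <- 10^best$par[3]
  structure(list(kon = kon, koff = koff, Rmax = Rmax, Kd = koff / kon,
                 rss = best$rss, converged = best$info %in% 1:4,
                 n_starts = length(starts)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: kon %.3g 1/M/s, koff %.3g 1/s, Kd %.3g M\n",
              x$kon, x$koff, x$Kd),
      sprintf("  Rmax %.3g, rss %.4g, converged: %s\n",
              x$Rmax, x$rss, x$converged), sep = "")
  invisible(x)
}

#' Equilibrium (steady-state) affinity cross-check
#'
#' Fits association plateaus against concentration with
#' `Req(C) = Rmax * C / (C + Kd)`, a closed-form alternative route to Kd
#' that ignores kinetics.
#'
#' @param sensorgrams referenced sensorgram list.
#' @return List with `Kd`, `Rmax`.
#' @export
fit_equilibrium <- function(sensorgrams) {
  concs <- vapply(sensorgrams, attr, 0, "conc_M")
  plateaus <- vapply(sensorgrams, function(s) {
    as_ <- s[s$phase == "association", ]
    mean(utils::tail(as_$response, max(3L, nrow(as_) %/% 50L)))
  }, 0)
  fit <- minpack.lm::nlsLM(plateaus ~ Rmax * concs / (concs + Kd),
                           start = list(Rmax = max(plateaus) * 1.2,
                                        Kd = stats::median(concs)),
                           lower = c(0, 0))
  as.list(coef(fit))
}

#' Write / read a sensorgram plate as CSV files
#'
#' One CSV per sensor with columns `time_s, response, phase, sensor_role,
#' conc_M`, plus a JSON manifest.
#'
#' @param plate a `bli_plate`.
#' @param dir output directory.
#' @export
write_plate_csv <- function(plate, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ci in seq_along(plate$wells)) {
    for (role in c("a", "b", "c", "d")) {
      sg <- plate$wells[[ci]][[role]]
      df <- data.frame(time_s = sg$time_s, response = sg$response,
                       phase = sg$phase, sensor_role = role,
                       conc_M = attr(sg, "conc_M"))
      f <- file.path(dir, sprintf("conc%02d_%s.csv", ci, role))
      write.csv(df, f, row.names = FALSE)
      files <- c(files, basename(f))
    }
  }
  manifest <- list(concentrations = plate$concentrations,
                   params = plate$params,
                   schedule = unclass(plate$schedule), files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_plate_csv
#' @param dir directory written by [write_plate_csv()].
#' @export
read_plate_csv <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  schedule <- do.call(bli_schedule, as.list(manifest$schedule))
  wells <- list(); referenced <- list()
  for (ci in seq_along(manifest$concentrations)) {
    w <- list()
    for (role in c("a", "b", "c", "d")) {
      df <- read.csv(file.path(dir, sprintf("conc%02d_%s.csv", ci, role)))
      w[[role]] <- new_sensorgram(df$time_s, df$response, df$conc_M[1],
                                  role, schedule)
    }
    wells[[ci]] <- w
    referenced[[ci]] <- double_reference(w$a, w$b, w$c, w$d)
  }
  structure(list(wells = wells, referenced = referenced,
                 concentrations = manifest$concentrations,
                 params = manifest$params, schedule = schedule),
            class = "bli_plate")
}
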