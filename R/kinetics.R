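#' Frame schedule for a dynamic PET acquisition
#'
#' @param durations_min Frame durations in minutes, in temporal order. The
#'   default (4 x 0.5, 4 x 1, 2 x 3, 2 x 4, 8 x 5 min) spans 0-60 min, the
#'   acquisition window of a dynamic PIB scan.
#' @param start_min Start of the first frame, minutes post-injection.
#'
#' @return Data frame of class `frame_schedule` with columns `frame_start`,
#'   `frame_end`, `frame_mid` (minutes).
#' @export
frame_schedule <- function(durations_min = c(rep(0.5, 4), rep(1, 4),
                                             rep(3, 2), rep(4, 2), rep(5, 8)),
                           start_min = 0) {
  if (any(durations_min <= 0)) stop("frame durations must be positive")
  ends <- start_min + cumsum(durations_min)
  starts <- c(start_min, ends[-length(ends)])
  structure(
    data.frame(frame_start = starts, frame_end = ends,
               frame_mid = (starts + ends) / 2),
    class = c("frame_schedule", "data.frame")
  )
}

#' Extend a schedule past 60 min (e.g. to 90 min with 5-min frames)
#' @param schedule A [frame_schedule()].
#' @param until_min Extend with `frame_min`-minute frames up to this time.
#' @param frame_min Duration of appended frames.
#' @return A `frame_schedule`.
#' @export
extend_schedule <- function(schedule, until_min = 90, frame_min = 5) {
  last <- max(schedule$frame_end)
  if (until_min <= last) return(schedule)
  extra <- seq(last, until_min, by = frame_min)
  frame_schedule(durations_min = c(schedule$frame_end - schedule$frame_start,
                                   diff(extra)),
                 start_min = min(schedule$frame_start))
}

# Instantaneous bi-exponential reference curve C_R(t) = A (e^{-l1 t} - e^{-l2 t})
.ref_curve_fun <- function(A, lambda1, lambda2) {
  function(t) A * (exp(-lambda1 * t) - exp(-lambda2 * t))
}

# Frame averages of a smooth curve by trapezoid on a fine grid (dt minutes)
.frame_average <- function(fun, schedule, dt = 0.01) {
  vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$frame_start[i]; b <- schedule$frame_end[i]
    grid <- seq(a, b, length.out = max(5L, ceiling((b - a) / dt) + 1L))
    y <- fun(grid)
    sum((y[-1] + y[-length(y)]) / 2 * diff(grid)) / (b - a)
  }, numeric(1))
}

#' Simulate a cerebellar reference-region time-activity curve
#'
#' The reference (cerebellar cortex) curve is modelled as a smooth
#' bi-exponential \eqn{C_R(t) = A (e^{-\lambda_1 t} - e^{-\lambda_2 t})}
#' with \eqn{\lambda_2 > \lambda_1 > 0}, which rises from zero, peaks at
#' \eqn{\ln(\lambda_2/\lambda_1)/(\lambda_2-\lambda_1)} (within the first
#' 10 min at defaults) and washes out. Frame values are frame averages of
#' the continuous curve.
#'
#' @param schedule A [frame_schedule()].
#' @param A Amplitude (activity units, kBq/mL semantics).
#' @param lambda1 Slow washout rate (1/min).
#' @param lambda2 Fast uptake rate (1/min), must exceed `lambda1`.
#'
#' @return A list of class `tac` with `schedule` and `activity`.
#' @export
simulate_reference_tac <- function(schedule = frame_schedule(), A = 100,
                                   lambda1 = 0.03, lambda2 = 0.6) {
  if (lambda2 <= lambda1) stop("lambda2 must exceed lambda1")
  if (lambda1 <= 0) stop("rates must be positive")
  fun <- .ref_curve_fun(A, lambda1, lambda2)
  tac(schedule, .frame_average(fun, schedule),
      params = list(A = A, lambda1 = lambda1, lambda2 = lambda2))
}

#' Construct a time-activity curve object
#' @param schedule A [frame_schedule()].
#' @param activity Numeric vector of frame activities, same length as the
#'   schedule, finite and non-negative.
#' @param params Optional generating parameters, kept for provenance.
#' @return A list of class `tac`.
#' @export
tac <- function(schedule, activity, params = NULL) {
  if (length(activity) != nrow(schedule)) {
    stop("activity length must match the number of frames")
  }
  if (any(!is.finite(activity)) || any(activity < -1e-9)) {
    stop("activity must be finite and non-negative")
  }
  structure(list(schedule = schedule, activity = as.numeric(activity),
                 params = params), class = "tac")
}

#' Kinetic parameters of the simplified reference tissue model
#'
#' @param R1 Delivery ratio K1/K1' (unitless), > 0.
#' @param k2 Efferent rate constant of the target tissue (1/min), > 0.
#' @param BPND Non-displaceable binding potential (unitless), >= 0.
#'   `k2a = k2 / (1 + BPND)` is derived; DVR = 1 + BPND.
#' @return List of class `kinetic_params`.
#' @export
kinetic_params <- function(R1 = 1, k2 = 0.15, BPND = 0) {
  if (R1 <= 0) stop("R1 must be positive")
  if (k2 <= 0) stop("k2 must be positive")
  if (BPND < 0) stop("BPND must be non-negative")
  structure(list(R1 = R1, k2 = k2, BPND = BPND, k2a = k2 / (1 + BPND)),
            class = "kinetic_params")
}

#' Simulate a target-region TAC under the simplified reference tissue model
#'
#' Uses the SRTM operational equation
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a}) \int_0^t C_R(u)
#'   e^{-k_{2a}(t-u)} du,}
#' with \eqn{k_{2a} = k_2/(1+BP_{ND})}. When the reference TAC carries its
#' bi-exponential parameters the convolution is evaluated in closed form;
#' otherwise the reference is resampled to a fine (<= 1 s) grid and the
#' convolution computed numerically. Frame values are frame averages.
#'
#' @param ref Reference [tac()] (ideally from [simulate_reference_tac()]).
#' @param params [kinetic_params()].
#' @param schedule Output schedule; defaults to the reference schedule.
#'
#' @return A `tac` for the target region. With `R1 = 1, BPND = 0` it equals
#'   the reference to numerical tolerance.
#' @export
simulate_srtm_tac <- function(ref, params, schedule = ref$schedule) {
  stopifnot(inherits(ref, "tac"), inherits(params, "kinetic_params"))
  R1 <- params$R1; k2 <- params$k2; k2a <- params$k2a
  coef <- k2 - R1 * k2a
  if (!is.null(ref$params) && all(c("A", "lambda1", "lambda2") %in% names(ref$params))) {
    A <- ref$params$A; l1 <- ref$params$lambda1; l2 <- ref$params$lambda2
    cr <- .ref_curve_fun(A, l1, l2)
    # closed-form \int_0^t e^{-l u} e^{-k2a (t-u)} du, stable as k2a -> l
    conv1 <- function(t, l) {
      if (abs(k2a - l) < 1e-10) t * exp(-l * t)
      else (exp(-l * t) - exp(-k2a * t)) / (k2a - l)
    }
    fun <- function(t) {
      R1 * cr(t) + coef * A * (vapply(t, conv1, numeric(1), l = l1) -
                               vapply(t, conv1, numeric(1), l = l2))
    }
    activity <- .frame_average(fun, schedule)
  } else {
    # numeric route: dense grid, trapezoid-discretised convolution
    dt <- 1 / 60  # 1 s in minutes
    tmax <- max(schedule$frame_end)
    grid <- seq(0, tmax, by = dt)
    cr_frame <- stats::approx(ref$schedule$frame_mid, ref$activity,
                              xout = grid, rule = 2)$y
    cr_frame[grid < min(ref$schedule$frame_start)] <- 0
    decay <- exp(-k2a * grid)
    conv <- dt * (stats::convolve(cr_frame, rev(decay), type = "open")[seq_along(grid)])
    ct <- R1 * cr_frame + coef * conv
    fun <- function(t) stats::approx(grid, ct, xout = t, rule = 2)$y
    activity <- .frame_average(fun, schedule)
  }
  tac(schedule, pmax(activity, 0), params = params)
}

#' Standard uptake value ratio over a late static window
#'
#' SUVR is the time-weighted mean target activity over frames whose
#' mid-times fall inside the window, divided by the same quantity for the
#' reference region. The default 30-60 min window is the conventional
#' static window for PIB.
#'
#' @param target,ref `tac` objects sharing a schedule.
#' @param window Numeric `c(start, end)` in minutes post-injection.
#'
#' @return SUVR (unitless, positive).
#' @export
compute_suvr <- function(target, ref, window = c(30, 60)) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!isTRUE(all.equal(target$schedule$frame_mid, ref$schedule$frame_mid))) {
    stop("target and reference TACs must share a frame schedule")
  }
  mid <- target$schedule$frame_mid
  sel <- mid >= window[1] & mid <= window[2]
  if (!any(sel)) stop("no frames with mid-time inside the SUVR window")
  w <- (target$schedule$frame_end - target$schedule$frame_start)[sel]
  ref_mean <- sum(w * ref$activity[sel]) / sum(w)
  if (ref_mean <= 0) stop("reference activity is zero in the SUVR window")
  (sum(w * target$activity[sel]) / sum(w)) / ref_mean
}

# cumulative trapezoid integral of y over x, from x[1]
.cumtrapz <- function(x, y) {
  c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(x)))
}

#' Reference Logan graphical analysis
#'
#' Estimates the distribution volume ratio (DVR) by ordinary least squares
#' on the Logan linearisation: for frame mid-times \eqn{T \ge t^*},
#' \deqn{\frac{\int_0^T C_T}{C_T(T)} = DVR \cdot
#'   \frac{\int_0^T C_R + C_R(T)/k_2'}{C_T(T)} + b,}
#' where the \eqn{C_R/k_2'} term is omitted when no population reference
#' efflux rate `k2_ref` is supplied. Cumulative integrals are trapezoidal
#' on frame mid-times.
#'
#' @param target,ref `tac` objects sharing a schedule.
#' @param t_star Linearisation start time (min p.i.), default 30.
#' @param k2_ref Optional population reference-region efflux rate (1/min);
#'   `NULL` omits the term.
#'
#' @return List with `dvr` (the regression slope) and `intercept`.
#' @export
compute_rlogan_dvr <- function(target, ref, t_star = 30, k2_ref = NULL) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!isTRUE(all.equal(target$schedule$frame_mid, ref$schedule$frame_mid))) {
    stop("target and reference TACs must share a frame schedule")
  }
  mid <- target$schedule$frame_mid
  int_t <- .cumtrapz(mid, target$activity)
  int_r <- .cumtrapz(mid, ref$activity)
  sel <- mid >= t_star
  if (sum(sel) < 3) stop("need at least 3 frames with mid-time >= t_star")
  ct <- target$activity[sel]
  if (any(ct <= 0)) stop("target activity must be positive after t_star")
  num_r <- int_r[sel]
  if (!is.null(k2_ref)) {
    if (k2_ref <= 0) stop("k2_ref must be positive")
    num_r <- num_r + ref$activity[sel] / k2_ref
  }
  x <- num_r / ct
  y <- int_t[sel] / ct
  if (stats::sd(x) < 1e-12) stop("Logan regressor is constant; regression singular")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(dvr = unname(fit$coefficients[2]), intercept = unname(fit$coefficients[1]))
}

#' Composite ROI definitions
#'
#' The cortical composite is the conventional global amyloid readout
#' (frontal, parietal, temporal, precuneus); the early composite covers
#' regions showing the earliest amyloid accumulation (isthmus cingulate,
#' precuneus, lateral orbitofrontal). Weights are volume weights,
#' normalised to sum to 1; defaults are equal weights.
#'
#' @param name `"cortical"` or `"early"`, or any custom name when `regions`
#'   is given.
#' @param regions Optional named numeric vector of positive region weights.
#'
#' @return List of class `composite_definition` with `name` and normalised
#'   `weights`.
#' @export
composite_definition <- function(name = c("cortical", "early"), regions = NULL) {
  if (is.null(regions)) {
    name <- match.arg(name)
    regions <- switch(name,
      cortical = c(frontal = 1, parietal = 1, temporal = 1, precuneus = 1),
      early = c(isthmus_cingulate = 1, precuneus = 1, lateral_orbitofrontal = 1)
    )
  }
  if (any(regions <= 0)) stop("region weights must be positive")
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stop("regions must be named")
  }
  structure(list(name = name, weights = regions / sum(regions)),
            class = "composite_definition")
}

#' Volume-weighted composite of regional values
#'
#' @param values Named numeric vector of regional metric values.
#' @param composite A [composite_definition()].
#' @return The weighted mean over the composite's member regions.
#' @export
aggregate_composite <- function(values, composite) {
  stopifnot(inherits(composite, "composite_definition"))
  members <- names(composite$weights)
  missing <- setdiff(members, names(values))
  if (length(missing)) {
    stop("missing region(s) for composite '", composite$name, "': ",
         paste(missing, collapse = ", "))
  }
  sum(composite$weights * values[members])
}

#' Centiloid calibration map
#'
#' An affine map from cortical-composite SUVR to the Centiloid scale,
#' anchored at the SUVR of amyloid-negative young controls (0 CL) and of
#' typical AD (100 CL).
#'
#' @param anchor_suvr_zero SUVR mapping to 0 CL.
#' @param anchor_suvr_hundred SUVR mapping to 100 CL (must be larger).
#' @return List of class `centiloid_map`.
#' @export
centiloid_map <- function(anchor_suvr_zero = 1.01, anchor_suvr_hundred = 1.90) {
  if (anchor_suvr_hundred <= anchor_suvr_zero) {
    stop("anchor_suvr_hundred must exceed anchor_suvr_zero")
  }
  structure(list(anchor_suvr_zero = anchor_suvr_zero,
                 anchor_suvr_hundred = anchor_suvr_hundred),
            class = "centiloid_map")
}

#' Convert cortical SUVR to Centiloid units
#' @param suvr_cortical Cortical-composite SUVR value(s).
#' @param map A [centiloid_map()].
#' @return Centiloid value(s).
#' @export
suvr_to_centiloid <- function(suvr_cortical, map = centiloid_map()) {
  stopifnot(inherits(map, "centiloid_map"))
  100 * (suvr_cortical - map$anchor_suvr_zero) /
    (map$anchor_suvr_hundred - map$anchor_suvr_zero)
}

#' Invert the Centiloid map back to cortical SUVR
#' @param cl Centiloid value(s).
#' @param map A [centiloid_map()].
#' @return Cortical SUVR value(s).
#' @export
centiloid_to_suvr <- function(cl, map = centiloid_map()) {
  stopifnot(inherits(map, "centiloid_map"))
  map$anchor_suvr_zero + cl / 100 * (map$anchor_suvr_hundred - map$anchor_suvr_zero)
}

#' Classify amyloid burden stratum from Centiloid value
#'
#' Low burden is CL <= 20.1 (the plaque-density positivity threshold),
#' intermediate is 20.1 < CL <= 49.4, and high is CL > 49.4 (the
#' AD-likelihood threshold). The boundaries belong to the lower stratum.
#'
#' @param cl Finite Centiloid value(s).
#' @return Character vector in `{"low", "intermediate", "high"}`.
#' @export
classify_burden_stratum <- function(cl) {
  if (any(!is.finite(cl))) stop("Centiloid values must be finite")
  ifelse(cl <= 20.1, "low", ifelse(cl <= 49.4, "intermediate", "high"))
}
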