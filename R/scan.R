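# Directional relaxed-coordinate-scan (RCS) driver.
#
# The driver sweeps the amide torsion omega from a minimum-energy isomer
# half a rotation to the opposite isomer against a pluggable 1-D energy
# backend, then refines the located barrier in progressively finer rounds.
# Geometry relaxation at fixed omega is the backend's responsibility, so
# the driver works identically over analytic test potentials and over a
# quantum-chemistry-calling backend.

#' Torsional energy backend
#'
#' Wraps a deterministic, 360-degree-periodic energy function of the amide
#' torsion.
#'
#' @param evaluate function of one numeric argument (omega, degrees)
#'   returning energy in kcal/mol; must accept vector input.
#' @param name backend label.
#' @param phase phase label (`"gas"` or `"water"`), informational.
#' @return object of class `"energy_backend"`.
#' @export
energy_backend <- function(evaluate, name = "backend", phase = "gas") {
  stopifnot(is.function(evaluate))
  out <- list(evaluate = evaluate, name = name, phase = phase)
  class(out) <- "energy_backend"
  out
}

#' Scan schedule
#'
#' Step sizes of the successive scan rounds, strictly decreasing. The
#' defaults mirror the study protocol: a 15-degree first sweep, a 2-degree
#' second round near the barrier, and a final round at 0.125 degrees (gas)
#' or 0.25 degrees (water).
#'
#' @param steps numeric vector of per-round step sizes, degrees.
#' @return object of class `"scan_schedule"`.
#' @export
scan_schedule <- function(steps = c(15, 2, 0.125)) {
  steps <- as.numeric(steps)
  if (length(steps) < 1L || any(!is.finite(steps)) || any(steps <= 0) ||
      any(diff(steps) >= 0)) {
    stop("schedule steps must be positive and strictly decreasing", call. = FALSE)
  }
  structure(list(steps = steps), class = "scan_schedule")
}

#' @rdname scan_schedule
#' @export
scan_schedule_water <- function() scan_schedule(c(15, 2, 0.25))

#' Run a directional relaxed coordinate scan
#'
#' Sweeps omega from `start` (a minimum-energy isomer) over 180 degrees of
#' arc in the requested direction, then refines a window of plus/minus one
#' previous-round step around the incumbent maximum at each finer step of
#' the schedule. All evaluated points are kept in the profile.
#'
#' @param backend an [energy_backend()].
#' @param start starting omega, degrees; must be a local minimum of the
#'   backend within one coarse step.
#' @param direction `"+"` (increasing omega) or `"-"`.
#' @param schedule a [scan_schedule()].
#' @return object of class `"scan_profile"`: list with `points`
#'   (data.frame of `s` — arc position from start, `omega`, `energy`,
#'   sorted along the direction), `direction`, `start`, `start_energy`,
#'   `start_isomer`, `round_estimates` (incumbent barrier height after
#'   each round), `n_eval` and `backend_name`.
#' @examples
#' b <- make_potential(data.frame(k = 2, v = 10, gamma = 0))
#' p <- run_rcs(b, start = 180, direction = "+")
#' find_ebg(p)
#' @export
run_rcs <- function(backend, start, direction = c("+", "-"),
                    schedule = scan_schedule()) {
  stopifnot(inherits(backend, "energy_backend"), inherits(schedule, "scan_schedule"))
  direction <- match.arg(direction)
  dir_sign <- if (direction == "+") 1 else -1
  steps <- schedule$steps
  n_eval <- 0L
  ev <- function(omega) {
    n_eval <<- n_eval + length(omega)
    val <- tryCatch(backend$evaluate(omega),
                    error = function(e) {
                      stop(sprintf("scan error at omega = %s: %s",
                                   paste(signif(omega, 8), collapse = ", "),
                                   conditionMessage(e)), call. = FALSE)
                    })
    if (any(!is.finite(val))) {
      stop(sprintf("scan error at omega = %s: backend returned non-finite energy",
                   paste(signif(omega[!is.finite(val)], 8), collapse = ", ")),
           call. = FALSE)
    }
    val
  }

  coarse <- steps[1]
  e_start <- ev(start)
  e_nbr <- ev(start + c(-1, 1) * coarse)
  if (any(e_nbr < e_start - 1e-9)) {
    stop(sprintf("start omega = %g is not a local minimum within one coarse step",
                 start), call. = FALSE)
  }

  # round 1: sweep the half rotation to the opposite isomer
  s <- seq(0, 180, by = coarse)
  if (s[length(s)] != 180) s <- c(s, 180)
  energy <- ev(start + dir_sign * s)
  pts_s <- s
  pts_e <- energy
  inc_idx <- which.max(pts_e)
  if (pts_s[inc_idx] < 1e-12 || pts_s[inc_idx] > 180 - 1e-12) {
    stop("flat or boundary-peaked profile: no interior maximum found",
         call. = FALSE)
  }
  round_estimates <- pts_e[inc_idx] - e_start

  # later rounds: refine +/- one previous step around the incumbent maximum
  if (length(steps) > 1L) {
    for (r in 2:length(steps)) {
      window <- steps[r - 1L]
      offs <- seq(-window, window, by = steps[r])
      s_new <- pts_s[inc_idx] + offs
      s_new <- s_new[s_new > 0 & s_new < 180]
      # skip arc positions already evaluated
      s_new <- s_new[vapply(s_new, function(x) all(abs(x - pts_s) > 1e-9), logical(1))]
      if (length(s_new) > 0L) {
        e_new <- ev(start + dir_sign * s_new)
        pts_s <- c(pts_s, s_new)
        pts_e <- c(pts_e, e_new)
      }
      inc_idx <- which.max(pts_e)
      round_estimates <- c(round_estimates, pts_e[inc_idx] - e_start)
    }
  }

  ord <- order(pts_s)
  points <- data.frame(s = pts_s[ord],
                       omega = start + dir_sign * pts_s[ord],
                       energy = pts_e[ord])
  w <- wrap_angle(start)
  start_isomer <- if (angular_distance(w, 180) <= 45) "trans"
                  else if (angular_distance(w, 0) <= 45) "cis"
                  else NA_character_
  out <- list(points = points, direction = direction, start = start,
              start_energy = e_start, start_isomer = start_isomer,
              round_estimates = round_estimates, n_eval = n_eval,
              backend_name = backend$name, schedule = schedule)
  class(out) <- "scan_profile"
  out
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf("<scan_profile> %s from omega = %g (%s), %d points, %d evaluations\n",
              x$direction, x$start,
              if (is.na(x$start_isomer)) "?" else x$start_isomer,
              nrow(x$points), x$n_eval))
  invisible(x)
}

#' Classify a barrier geometry as syn or anti
#'
#' Barriers nearer (in angular distance) to omega = +/-60 are syn, those
#' nearer +/-120 are anti. An exact tie (|omega| = 0, 90 or 180) is
#' classified syn with the ambiguity flag set, so batch runs stay alive.
#'
#' @param omega_star barrier torsion, degrees in (-180, 180].
#' @return list with `type` (`"syn"`/`"anti"`) and `ambiguous` (logical).
#' @examples
#' classify_ebg(62)   # syn
#' classify_ebg(-118) # anti
#' @export
classify_ebg <- function(omega_star) {
  stopifnot(length(omega_star) == 1L, is.finite(omega_star))
  d_syn <- min(angular_distance(omega_star, 60), angular_distance(omega_star, -60))
  d_anti <- min(angular_distance(omega_star, 120), angular_distance(omega_star, -120))
  # 0 and 180 are equidistant between the two references of their nearer
  # class (the +/- direction is undetermined there), so they are flagged too
  planar <- planarity_deviation(omega_star) == 0
  if (d_syn == d_anti) {
    list(type = "syn", ambiguous = TRUE)
  } else {
    list(type = if (d_syn < d_anti) "syn" else "anti", ambiguous = planar)
  }
}

#' Locate the energy-barrier geometry of a scan profile
#'
#' The EBG is the maximum-energy point of the profile, used as a
#' transition-state proxy; its height is reported relative to the scan's
#' starting minimum.
#'
#' @param profile a `"scan_profile"` from [run_rcs()].
#' @return object of class `"ebg"`: list with `type`, `ambiguous`,
#'   `direction`, `start_isomer`, `omega_star` (wrapped to (-180, 180]),
#'   `e_star` (kcal/mol above the scan start) and `energy` (absolute).
#' @export
find_ebg <- function(profile) {
  stopifnot(inherits(profile, "scan_profile"))
  pts <- profile$points
  idx <- which.max(pts$energy)
  if (pts$s[idx] <= min(pts$s) + 1e-12 || pts$s[idx] >= max(pts$s) - 1e-12) {
    stop("barrier at profile boundary: no interior maximum", call. = FALSE)
  }
  omega_star <- wrap_angle(pts$omega[idx])
  cls <- classify_ebg(omega_star)
  out <- list(type = cls$type, ambiguous = cls$ambiguous,
              direction = profile$direction,
              start_isomer = profile$start_isomer,
              omega_star = omega_star,
              e_star = pts$energy[idx] - profile$start_energy,
              energy = pts$energy[idx])
  class(out) <- "ebg"
  out
}

#' @export
print.ebg <- function(x, ...) {
  cat(sprintf("<ebg> %s%s at omega = %.3f, %.4f kcal/mol above %s start%s\n",
              x$type, x$direction, x$omega_star, x$e_star,
              if (is.na(x$start_isomer)) "scan" else x$start_isomer,
              if (x$ambiguous) " (ambiguous)" else ""))
  invisible(x)
}

# locate a minimum of the backend near a reference angle
locate_minimum <- function(backend, near, halfwidth = 60) {
  grid <- seq(near - halfwidth, near + halfwidth, by = 1)
  e <- backend$evaluate(grid)
  i <- which.min(e)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(backend$evaluate, interval = c(lo, hi))
  opt$minimum
}

#' Directional barrier set for one compound and phase
#'
#' Runs the RCS protocol from both minimum-energy isomers: trans-start
#' scans (which locate the syn barriers near omega = +/-60) and cis-start
#' scans (the anti barriers near +/-120), in both rotation senses. For
#' symmetric compounds (only hydrogens on both alpha carbons) only the
#' positive sense is scanned and the mirror entries are marked absent,
#' matching the study's "not determined" convention. Cis-start barrier
#' heights are additionally re-referenced to the trans minimum
#' (`e_rel_trans`) using the cis backend's own well energies.
#'
#' @param backend_trans backend used for trans-start scans.
#' @param backend_cis backend used for cis-start scans (defaults to
#'   `backend_trans`; a separate surface emulates relaxation hysteresis).
#' @param symmetric logical; scan only the positive sense and mirror as
#'   absent.
#' @param schedule a [scan_schedule()].
#' @return data.frame with one row per (start isomer, direction):
#'   `start_isomer`, `direction`, `type`, `omega_star`, `e_star` (relative
#'   to own start), `e_rel_trans`, `ambiguous`, `n_eval`; absent entries
#'   hold `NA`.
#' @export
barrier_set <- function(backend_trans, backend_cis = backend_trans,
                        symmetric = FALSE, schedule = scan_schedule()) {
  stopifnot(inherits(backend_trans, "energy_backend"),
            inherits(backend_cis, "energy_backend"))
  trans_min <- locate_minimum(backend_trans, 180)
  cis_min <- locate_minimum(backend_cis, 0)
  # well offset on the cis-start surface, for re-referencing to trans
  cis_offset <- backend_cis$evaluate(cis_min) -
    backend_cis$evaluate(locate_minimum(backend_cis, 180))
  directions <- if (symmetric) "+" else c("+", "-")
  rows <- list()
  for (iso in c("trans", "cis")) {
    backend <- if (iso == "trans") backend_trans else backend_cis
    start <- if (iso == "trans") trans_min else cis_min
    for (dd in c("+", "-")) {
      key <- paste0(iso, dd)
      if (!dd %in% directions) {
        rows[[key]] <- data.frame(start_isomer = iso, direction = dd,
                                  type = NA_character_, omega_star = NA_real_,
                                  e_star = NA_real_, e_rel_trans = NA_real_,
                                  ambiguous = NA, n_eval = NA_integer_)
        next
      }
      prof <- tryCatch(
        run_rcs(backend, start, dd, schedule),
        error = function(e) {
          stop(sprintf("[%s-start, %s] %s", iso, dd, conditionMessage(e)),
               call. = FALSE)
        })
      ebg <- tryCatch(
        find_ebg(prof),
        error = function(e) {
          stop(sprintf("[%s-start, %s] %s", iso, dd, conditionMessage(e)),
               call. = FALSE)
        })
      rows[[key]] <- data.frame(
        start_isomer = iso, direction = dd, type = ebg$type,
        omega_star = ebg$omega_star, e_star = ebg$e_star,
        e_rel_trans = ebg$e_star + if (iso == "cis") cis_offset else 0,
        ambiguous = ebg$ambiguous, n_eval = prof$n_eval)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
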