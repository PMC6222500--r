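# Synthetic-data generators with known ground truth: Fourier torsion
# potentials (the cis/trans double well), additive conformer-energy tables
# with injected steric offsets, and idealized backbone fragments with
# prescribed dihedrals. Every generator is reproducible for a fixed seed.

#' Analytic Fourier torsion potential
#'
#' Builds an [energy_backend()] evaluating
#' `E(omega) = offset + sum_k Vk/2 * (1 - cos(k * (omega - gamma_k)))`.
#' A dominant k = 2 term produces the two wells near omega = 0 (cis) and
#' 180 (trans); a k = 1 term biases one well (the cis/trans gap); odd
#' phases make the +/- barriers inequivalent, emulating the asymmetry
#' introduced by chiral substitution.
#'
#' @param terms data.frame with columns `k` (positive integer order), `v`
#'   (barrier coefficient, kcal/mol) and optionally `gamma` (phase,
#'   degrees; default 0). At least one term must have `k >= 2`, otherwise
#'   the surface cannot hold two wells.
#' @param offset constant energy offset, kcal/mol.
#' @param name,phase backend labels.
#' @return an `"energy_backend"`, periodic with period 360 degrees.
#' @examples
#' b <- make_potential(data.frame(k = 2, v = 10, gamma = 0))
#' b$evaluate(c(0, 90, 180)) # 0, 10, 0
#' @export
make_potential <- function(terms, offset = 0, name = "fourier", phase = "gas") {
  stopifnot(is.data.frame(terms))
  if (nrow(terms) == 0L) stop("`terms` must contain at least one term", call. = FALSE)
  if (!all(c("k", "v") %in% names(terms))) {
    stop("`terms` needs columns `k` and `v`", call. = FALSE)
  }
  if (!"gamma" %in% names(terms)) terms$gamma <- 0
  k <- as.numeric(terms$k)
  v <- as.numeric(terms$v)
  gamma <- as.numeric(terms$gamma)
  if (any(k < 1) || any(k != round(k))) {
    stop("Fourier orders `k` must be positive integers", call. = FALSE)
  }
  if (!any(k >= 2)) {
    stop("at least one term with k >= 2 is required for a two-well surface",
         call. = FALSE)
  }
  force(offset)
  evaluate <- function(omega) {
    rad <- pi / 180
    out <- rep(offset, length(omega))
    for (j in seq_along(k)) {
      out <- out + v[j] / 2 * (1 - cos(k[j] * (omega - gamma[j]) * rad))
    }
    out
  }
  energy_backend(evaluate, name = name, phase = phase)
}

# parabolic vertex through three equally spaced points
quad_refine <- function(x0, h, e_lo, e_mid, e_hi) {
  denom <- e_lo - 2 * e_mid + e_hi
  if (abs(denom) < 1e-300) return(c(x = x0, e = e_mid))
  dx <- 0.5 * h * (e_lo - e_hi) / denom
  e <- e_mid - 0.125 * (e_lo - e_hi)^2 / denom
  c(x = x0 + dx, e = e)
}

#' Dense-grid ground truth for a two-well torsion potential
#'
#' Locates both minima and both maxima of a periodic backend on a dense
#' grid (default 0.001 degrees, an order of magnitude below the finest
#' scan step) with local quadratic refinement, and books the directional
#' barrier heights relative to each well. Serves as the independent oracle
#' for the scan driver.
#'
#' @param backend an `"energy_backend"`.
#' @param grid_step grid resolution, degrees.
#' @return list with `omega_min_trans`, `omega_min_cis`, `e_min_trans`,
#'   `e_min_cis`, and `barriers`: a data.frame with one row per maximum —
#'   `direction_from_trans`, `direction_from_cis` (`"+"`/`"-"`),
#'   `omega_star`, `energy`, `height_vs_trans`, `height_vs_cis`, `type`,
#'   `ambiguous`.
#' @export
ground_truth <- function(backend, grid_step = 0.001) {
  stopifnot(inherits(backend, "energy_backend"))
  omega <- seq(-180 + grid_step, 180, by = grid_step)
  n <- length(omega)
  e <- backend$evaluate(omega)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  is_min <- e < e[prv] & e <= e[nxt]
  is_max <- e > e[prv] & e >= e[nxt]
  i_min <- which(is_min)
  i_max <- which(is_max)
  if (length(i_min) != 2L || length(i_max) != 2L) {
    stop(sprintf("expected exactly two minima and two maxima per period, found %d/%d",
                 length(i_min), length(i_max)), call. = FALSE)
  }
  refine <- function(i) {
    quad_refine(omega[i], grid_step, e[prv[i]], e[i], e[nxt[i]])
  }
  mins <- t(vapply(i_min, refine, numeric(2)))
  maxs <- t(vapply(i_max, refine, numeric(2)))
  # assign wells by proximity to the planar references
  d180 <- angular_distance(mins[, "x"], 180)
  trans_row <- which.min(d180)
  cis_row <- setdiff(1:2, trans_row)
  w_trans <- unname(wrap_angle(mins[trans_row, "x"]))
  w_cis <- unname(wrap_angle(mins[cis_row, "x"]))
  e_trans <- unname(mins[trans_row, "e"])
  e_cis <- unname(mins[cis_row, "e"])
  # a maximum on the arc swept by increasing omega from the trans well
  # before reaching the cis well is the "+" barrier from trans (and the
  # "-" barrier from cis)
  arc_to_cis <- (w_cis - w_trans) %% 360
  barriers <- do.call(rbind, lapply(1:2, function(r) {
    wm <- wrap_angle(maxs[r, "x"])
    a <- (wm - w_trans) %% 360
    from_trans <- if (a < arc_to_cis) "+" else "-"
    cls <- classify_ebg(wm)
    data.frame(direction_from_trans = from_trans,
               direction_from_cis = if (from_trans == "+") "-" else "+",
               omega_star = wm,
               energy = maxs[r, "e"],
               height_vs_trans = maxs[r, "e"] - e_trans,
               height_vs_cis = maxs[r, "e"] - e_cis,
               type = cls$type, ambiguous = cls$ambiguous)
  }))
  list(omega_min_trans = w_trans, omega_min_cis = w_cis,
       e_min_trans = e_trans, e_min_cis = e_cis, barriers = barriers)
}

#' Synthetic additive conformer-energy table with injected steric offsets
#'
#' Generates optimized-energy records that are exactly additive
#' (base + increments) plus a known, non-negative steric offset per
#' record, emulating the statistical structure of the study's steric
#' tables: an additive baseline with positive steric deviations that grow
#' with substitution count. Recovering the offsets through
#' [steric_table()] validates the additivity pipeline.
#'
#' Defaults reproduce the study conditions: the printed base energies of
#' the unsubstituted scaffold and the printed tert-butyl increments.
#' Random offsets are half-normal, scaled by the total substitution count;
#' the base compound always has offset zero.
#'
#' @param base data.frame(`isomer`, `phase`, `energy`) of scaffold base
#'   energies; default: the packaged study values.
#' @param increments data.frame(`attachment`, `phase`, `value`); default:
#'   increments derived from the packaged small-molecule tables.
#' @param offsets optional data.frame(`compound`, `isomer`, `phase`,
#'   `offset`) of prescribed steric offsets; unspecified records get 0
#'   when `seed` is `NULL`, otherwise seeded half-normal draws.
#' @param seed integer seed for random offsets (ignored when `offsets`
#'   covers everything).
#' @param offset_scale half-normal scale per substitution, kcal/mol.
#' @param compounds N-codes to include.
#' @param isomers,phases blocks to generate.
#' @return list with `records` (data.frame `compound`, `isomer`, `phase`,
#'   `opt_e`), `offsets` (ground-truth data.frame, same keying) and
#'   `model` (the `"additivity_model"` used).
#' @export
make_energy_table <- function(base = NULL, increments = NULL, offsets = NULL,
                              seed = NULL, offset_scale = 1.5,
                              compounds = model_compound_codes(),
                              isomers = c("trans", "cis"),
                              phases = c("gas", "water")) {
  if (is.null(base) || is.null(increments)) {
    study <- study_additivity_model()
    if (is.null(base)) base <- study$base
    if (is.null(increments)) increments <- study$increments
  }
  base <- base[base$isomer %in% isomers & base$phase %in% phases, , drop = FALSE]
  model <- additivity_model(base, increments)
  grid <- expand.grid(compound = compounds, isomer = isomers, phase = phases,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  off <- rep(0, n)
  if (!is.null(seed)) {
    set.seed(seed)
    counts <- t(vapply(grid$compound, substitution_counts, integer(2)))
    total <- counts[, "n_n"] + counts[, "n_c"]
    off <- total * abs(stats::rnorm(n, 0, offset_scale))
  }
  if (!is.null(offsets)) {
    stopifnot(all(c("compound", "isomer", "phase", "offset") %in% names(offsets)))
    key <- paste(grid$compound, grid$isomer, grid$phase)
    okey <- paste(offsets$compound, offsets$isomer, offsets$phase)
    hit <- match(key, okey)
    off[!is.na(hit)] <- offsets$offset[hit[!is.na(hit)]]
  }
  # the base compound is its own reference: offset 0 by construction
  off[grid$compound == "N0000"] <- 0
  opt_e <- numeric(n)
  for (i in seq_len(n)) {
    opt_e[i] <- additive_energy(model, grid$compound[i], grid$isomer[i],
                                grid$phase[i]) + off[i]
  }
  records <- cbind(grid, opt_e = opt_e)
  truth <- cbind(grid, offset = off)
  list(records = records, offsets = truth, model = model)
}

# NeRF internal-coordinate placement: position D such that |CD| = bond,
# angle(BCD) = theta and torsion(A,B,C,D) = chi.
place_atom <- function(A, B, C, bond, theta, chi) {
  rad <- pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(theta * rad),
          bond * sin(theta * rad) * cos(chi * rad),
          bond * sin(theta * rad) * sin(chi * rad))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# canonical internal coordinates of the dipeptide-ester fragment; only
# the four backbone torsions vary
fragment_geometry <- list(
  bonds = c(n1_ca1 = 1.47, ca1_c1 = 1.52, c1_n2 = 1.33, n2_ca2 = 1.47,
            ca2_c2 = 1.52, c2_o3 = 1.34, c1_o1 = 1.23, n2_h = 1.01),
  angles = c(at_ca1 = 109.5, at_c1 = 120, at_n2 = 120, at_ca2 = 109.5,
             at_c2 = 120, c1_o1 = 120, n2_h = 120)
)

#' Idealized backbone fragment with prescribed dihedrals
#'
#' Builds a minimal dipeptide-ester backbone (amino N, two alpha carbons,
#' amide C/N, ester carbonyl and ester O, plus the amide carbonyl O and
#' amide H) by internal-coordinate construction with fixed canonical bond
#' lengths and angles, such that [backbone_dihedrals()] returns the
#' requested torsions. Intended for testing torsion code, not for
#' energetics.
#'
#' @param dihedrals named numeric vector with `psi_n`, `omega`, `phi_c`,
#'   `psi_c` in degrees (each in (-180, 180]).
#' @param label structure label.
#' @return list with `structure` (an `"xyz_structure"`) and `map` (an
#'   [atom_map()] with torsion quadruples, H-bond indices and an
#'   amide-frame set).
#' @examples
#' frag <- make_backbone_fragment(c(psi_n = 12.8, omega = 178.3,
#'                                  phi_c = 175.6, psi_c = -179.3))
#' backbone_dihedrals(frag$structure, frag$map)
#' @export
make_backbone_fragment <- function(dihedrals = c(psi_n = 180, omega = 180,
                                                 phi_c = 180, psi_c = 180),
                                   label = "synthetic backbone fragment") {
  need <- c("psi_n", "omega", "phi_c", "psi_c")
  if (!all(need %in% names(dihedrals))) {
    stop("`dihedrals` must name psi_n, omega, phi_c and psi_c", call. = FALSE)
  }
  dh <- as.numeric(dihedrals[need])
  if (any(!is.finite(dh)) || any(dh <= -180) || any(dh > 180)) {
    stop("dihedrals must be finite and in (-180, 180]", call. = FALSE)
  }
  names(dh) <- need
  g <- fragment_geometry
  xyz <- matrix(NA_real_, 9, 3)
  # seed triad: amino N, first alpha C, amide C in the xy-plane
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(g$bonds[["n1_ca1"]], 0, 0)
  ang <- g$angles[["at_ca1"]] * pi / 180
  xyz[3, ] <- xyz[2, ] + g$bonds[["ca1_c1"]] * c(-cos(ang), sin(ang), 0)
  xyz[4, ] <- place_atom(xyz[1, ], xyz[2, ], xyz[3, ], g$bonds[["c1_n2"]],
                         g$angles[["at_c1"]], dh[["psi_n"]])
  xyz[5, ] <- place_atom(xyz[2, ], xyz[3, ], xyz[4, ], g$bonds[["n2_ca2"]],
                         g$angles[["at_n2"]], dh[["omega"]])
  xyz[6, ] <- place_atom(xyz[3, ], xyz[4, ], xyz[5, ], g$bonds[["ca2_c2"]],
                         g$angles[["at_ca2"]], dh[["phi_c"]])
  xyz[7, ] <- place_atom(xyz[4, ], xyz[5, ], xyz[6, ], g$bonds[["c2_o3"]],
                         g$angles[["at_c2"]], dh[["psi_c"]])
  # amide carbonyl O opposite the amide N, amide H opposite the alpha C
  xyz[8, ] <- place_atom(xyz[1, ], xyz[2, ], xyz[3, ], g$bonds[["c1_o1"]],
                         g$angles[["c1_o1"]], wrap_angle(dh[["psi_n"]] + 180))
  xyz[9, ] <- place_atom(xyz[2, ], xyz[3, ], xyz[4, ], g$bonds[["n2_h"]],
                         g$angles[["n2_h"]], wrap_angle(dh[["omega"]] + 180))
  structure <- xyz_structure(c("N", "C", "C", "N", "C", "C", "O", "O", "H"),
                             xyz, label = label)
  map <- atom_map(psi_n = c(1, 2, 3, 4), omega = c(2, 3, 4, 5),
                  phi_c = c(3, 4, 5, 6), psi_c = c(4, 5, 6, 7),
                  hbond_donor = 1, amide_h = 9, frame = c(3, 4, 8))
  list(structure = structure, map = map, dihedrals = dh)
}
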