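# Molecule specifications: segments, stiffnesses, serialization.

#' Segment of a molecule's intrinsic shape
#'
#' @param kind one of `"helix"`, `"arc"`, `"straight"`.
#' @param n_bp number of basepair steps in the segment (>= 1).
#' @param bend_total total effective bend over the segment, degrees; the bend
#'   angle per basepair is `bend_total / n_bp`. Must be 0 for straight segments.
#' @param pitch_over_circumf signed pitch-to-circumference ratio of the
#'   intrinsic helix (0 for planar arcs; positive = left-handed).
#' @return object of class `segment_spec`.
#' @export
segment_spec <- function(kind = c("helix", "arc", "straight"), n_bp,
                         bend_total = 0, pitch_over_circumf = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(n_bp), length(n_bp) == 1L, n_bp >= 1,
            n_bp == round(n_bp), is.finite(bend_total),
            is.finite(pitch_over_circumf))
  if (kind == "straight" && (bend_total != 0 || pitch_over_circumf != 0))
    stop("straight segments must have bend_total = 0 and pitch_over_circumf = 0")
  if (kind == "arc" && pitch_over_circumf != 0)
    stop("arc segments must have pitch_over_circumf = 0")
  if (kind != "straight" && bend_total <= 0)
    stop("bent segments need bend_total > 0 (degrees)")
  structure(list(kind = kind, n_bp = as.integer(n_bp),
                 bend_total = bend_total,
                 pitch_over_circumf = pitch_over_circumf),
            class = "segment_spec")
}

#' Stiffness parameters of the diagonal-quadratic energy
#'
#' Six stiffnesses: rotational `K1, K2, K3` (units RT per squared Cayley
#' component) and translational `A1, A2, A3` (RT per squared Angstrom), plus a
#' global scale factor applied to all six. Defaults are the baseline model:
#' `K1 = K2 = 46.3/0.34` RT (a 46.3 nm persistence length at 3.4 Angstrom
#' rise), `K3 = 1.5 K1`, and `(A1, A2, A3) = (14, 24, 85)` RT/Angstrom^2.
#' An isotropic rod (`K2 = K1`) is assumed throughout the baseline analyses.
#'
#' @param K1,K2,K3 rotational stiffnesses, RT units; `K2` defaults to `K1`
#'   and `K3` to `K3_over_K1 * K1`.
#' @param K3_over_K1 twist-to-bend stiffness ratio used when `K3` is missing.
#' @param A translational stiffnesses `(A1, A2, A3)`, RT/Angstrom^2.
#' @param scale_beta dimensionless multiplier applied to all six stiffnesses.
#' @param extensible if `FALSE`, translations are frozen at their intrinsic
#'   values when sampling (inextensible-unshearable model).
#' @return object of class `stiffness_set`.
#' @export
stiffness_set <- function(K1 = 46.3 / 0.34, K2 = K1, K3 = NULL,
                          K3_over_K1 = 1.5, A = c(14, 24, 85),
                          scale_beta = 1, extensible = TRUE) {
  if (is.null(K3)) K3 <- K3_over_K1 * K1
  stopifnot(is.numeric(A), length(A) == 3L)
  vals <- c(K1, K2, K3, A, scale_beta)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all stiffnesses and scale_beta must be positive and finite")
  structure(list(K = c(K1, K2, K3), A = as.numeric(A),
                 scale_beta = scale_beta, extensible = isTRUE(extensible)),
            class = "stiffness_set")
}

#' Molecule specification
#'
#' A molecule is a list of intrinsic-shape segments (any trailing basepairs
#' not covered by the segments are an implicit straight filler), a total
#' basepair count `N`, a helical repeat, and a stiffness set. The intrinsic
#' shape has `N` steps; step `N` connects frame `N` to the fictitious closure
#' frame `N + 1`.
#'
#' @param segments list of [segment_spec()] objects.
#' @param N total basepair count.
#' @param helical_repeat basepairs per intrinsic twist turn (default 10.5).
#' @param stiffness a [stiffness_set()].
#' @param ell basepair spacing, Angstrom.
#' @return object of class `molecule_spec`.
#' @export
molecule_spec <- function(segments, N, helical_repeat = 10.5,
                          stiffness = stiffness_set(), ell = 3.4) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  stopifnot(is.list(segments), all(vapply(segments, inherits, TRUE, "segment_spec")),
            is.numeric(N), length(N) == 1L, N == round(N), N >= 2,
            is.finite(helical_repeat), helical_repeat > 0,
            inherits(stiffness, "stiffness_set"), ell > 0)
  if (sum(vapply(segments, function(s) s$n_bp, 1L)) > N)
    stop("segment basepair counts exceed N")
  structure(list(segments = segments, N = as.integer(N),
                 helical_repeat = helical_repeat, stiffness = stiffness,
                 ell = ell),
            class = "molecule_spec")
}

#' Canonical bend-plus-straight molecule
#'
#' The workhorse construct of the cyclization analyses: a bend of
#' `bend_deg` degrees spread over `bend_bp` basepairs (planar if
#' `pitch_over_circumf = 0`, helical otherwise), followed by a straight
#' segment filling out the remaining `N - bend_bp` steps.
#'
#' @param N total basepair count.
#' @param bend_deg total bend angle, degrees.
#' @param bend_bp basepairs over which the bend occurs (default 63).
#' @param pitch_over_circumf signed non-planarity ratio of the bend.
#' @param helical_repeat basepairs per turn.
#' @param stiffness a [stiffness_set()].
#' @return a [molecule_spec()].
#' @export
bent_molecule <- function(N, bend_deg = 90, bend_bp = 63,
                          pitch_over_circumf = 0, helical_repeat = 10.5,
                          stiffness = stiffness_set()) {
  seg <- if (bend_deg == 0) {
    segment_spec("straight", bend_bp)
  } else if (pitch_over_circumf == 0) {
    segment_spec("arc", bend_bp, bend_total = bend_deg)
  } else {
    segment_spec("helix", bend_bp, bend_total = bend_deg,
                 pitch_over_circumf = pitch_over_circumf)
  }
  molecule_spec(list(seg), N = N, helical_repeat = helical_repeat,
                stiffness = stiffness)
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf("molecule_spec: N = %d bp, helical repeat %.3f bp/turn\n",
              x$N, x$helical_repeat))
  for (s in x$segments)
    cat(sprintf("  %-8s %3d bp  bend %6.2f deg  pitch/circumf %+.3f\n",
                s$kind, s$n_bp, s$bend_total, s$pitch_over_circumf))
  filler <- x$N - sum(vapply(x$segments, function(s) s$n_bp, 1L))
  if (filler > 0) cat(sprintf("  straight %3d bp  (implicit filler)\n", filler))
  k <- x$stiffness
  cat(sprintf("  K = (%.2f, %.2f, %.2f) RT, A = (%g, %g, %g) RT/A^2, scale %g%s\n",
              k$K[1], k$K[2], k$K[3], k$A[1], k$A[2], k$A[3], k$scale_beta,
              if (k$extensible) "" else ", inextensible"))
  invisible(x)
}

.spec_to_list <- function(spec) {
  list(
    N = spec$N,
    helical_repeat = spec$helical_repeat,
    ell = spec$ell,
    segments = lapply(spec$segments, function(s)
      list(kind = s$kind, n_bp = s$n_bp, bend_total_deg = s$bend_total,
           pitch_over_circumf = s$pitch_over_circumf)),
    stiffness = list(K1_RT = spec$stiffness$K[1], K2_RT = spec$stiffness$K[2],
                     K3_RT = spec$stiffness$K[3],
                     A_RT_per_A2 = spec$stiffness$A,
                     scale_beta = spec$stiffness$scale_beta,
                     extensible = spec$stiffness$extensible)
  )
}

.spec_from_list <- function(x) {
  need <- function(field, where = x) {
    if (is.null(where[[field]])) stop("molecule config is missing field: ", field)
    where[[field]]
  }
  st <- x$stiffness
  stiff <- if (is.null(st)) stiffness_set() else {
    K1 <- if (!is.null(st$K1_RT)) st$K1_RT
          else if (!is.null(st$persistence_nm)) stiffness_from_persistence(st$persistence_nm)
          else 46.3 / 0.34
    K3 <- if (!is.null(st$K3_RT)) st$K3_RT
          else (if (!is.null(st$K3_over_K1)) st$K3_over_K1 else 1.5) * K1
    stiffness_set(K1 = K1,
                  K2 = if (!is.null(st$K2_RT)) st$K2_RT else K1,
                  K3 = K3,
                  A = if (!is.null(st$A_RT_per_A2)) unlist(st$A_RT_per_A2) else c(14, 24, 85),
                  scale_beta = if (!is.null(st$scale_beta)) st$scale_beta else 1,
                  extensible = if (!is.null(st$extensible)) st$extensible else TRUE)
  }
  segs <- lapply(need("segments"), function(s)
    segment_spec(need("kind", s), need("n_bp", s),
                 bend_total = if (!is.null(s$bend_total_deg)) s$bend_total_deg else 0,
                 pitch_over_circumf = if (!is.null(s$pitch_over_circumf)) s$pitch_over_circumf else 0))
  molecule_spec(segs, N = need("N"),
                helical_repeat = if (!is.null(x$helical_repeat)) x$helical_repeat else 10.5,
                stiffness = stiff,
                ell = if (!is.null(x$ell)) x$ell else 3.4)
}

#' Read / write molecule specifications
#'
#' Molecule specs serialize to YAML (or JSON, by file extension) with fields
#' `N`, `helical_repeat`, `segments` (kind, n_bp, bend_total_deg,
#' pitch_over_circumf) and a `stiffness` block that accepts either `K1_RT` or
#' `persistence_nm`, plus `K3_over_K1` / `K3_RT`, `A_RT_per_A2`, `scale_beta`
#' and `extensible`.
#'
#' @param spec a [molecule_spec()].
#' @param file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_molecule` returns a [molecule_spec()]; `write_molecule`
#'   returns `file` invisibly.
#' @export
write_molecule <- function(spec, file) {
  stopifnot(inherits(spec, "molecule_spec"))
  x <- .spec_to_list(spec)
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, file)
  }
  invisible(file)
}

#' @rdname write_molecule
#' @export
read_molecule <- function(file) {
  x <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = FALSE)
       else yaml::read_yaml(file)
  .spec_from_list(x)
}
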