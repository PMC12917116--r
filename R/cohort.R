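# Cohorts of phantoms with controlled parameter variation and deterministic
# pathology planting (exact prevalences, not Bernoulli draws).

COHORT_NUMERIC_KEYS <- c("lordosis_angle", "disc_height", "noise_sd",
                         "rotation_x", "rotation_y", "rotation_z",
                         "translation_x", "translation_y", "translation_z")

#' Generate a cohort of synthetic phantoms
#'
#' Samples per-phantom parameters uniformly from the requested ranges and
#' plants pathology in an exact, deterministic fraction of the cohort:
#' `round(prop * n)` phantoms receive the condition, chosen by a seeded
#' permutation, so planted prevalences are reproducible and exact.
#'
#' @param n Number of phantoms.
#' @param base_spec A [phantom_spec()] providing all unvaried parameters.
#' @param variation Named list. Numeric entries are `c(lo, hi)` ranges for
#'   `lordosis_angle`, `disc_height`, `noise_sd`, `rotation_x/y/z`,
#'   `translation_x/y/z`. Pathology entries:
#'   `canal_stenosis = list(prop, level, range)` (canal diameter range, mm),
#'   `recess_stenosis = list(prop, level, side, height_range)` and/or
#'   `angle_range`, and `herniation = list(prop, level, extent_range, zone)`.
#' @param seed Integer seed; the same `(n, base_spec, variation, seed)`
#'   reproduce the cohort exactly.
#' @param intensity Passed to [generate_phantom()].
#' @return List of length `n`; each element has `spec`, `labels`,
#'   `intensity`, `truth`.
#' @export
phantom_cohort <- function(n, base_spec, variation = list(), seed = 1L,
                           intensity = FALSE) {
  if (n < 1) stop("n must be >= 1")
  num_keys <- intersect(names(variation), COHORT_NUMERIC_KEYS)
  path_keys <- setdiff(names(variation), COHORT_NUMERIC_KEYS)
  unknown <- setdiff(path_keys, c("canal_stenosis", "recess_stenosis",
                                  "herniation"))
  if (length(unknown)) stop("unknown variation key(s): ",
                            paste(unknown, collapse = ", "))
  for (key in num_keys) {
    r <- variation[[key]]
    if (length(r) != 2 || r[1] > r[2]) stop("InvalidRange: ", key)
    if (key %in% c("disc_height") && r[1] <= 0) stop("InvalidRange: ", key)
    if (key == "noise_sd" && r[1] < 0) stop("InvalidRange: noise_sd")
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  draw <- function(range, m) {
    if (m == 1) mean(range) else stats::runif(m, range[1], range[2])
  }
  num_draws <- lapply(variation[num_keys], draw, m = n)

  planted <- function(prop) {
    count <- round(prop * n)
    idx <- sample.int(n)
    seq_len(n) %in% idx[seq_len(count)]
  }
  cs <- variation$canal_stenosis
  rs <- variation$recess_stenosis
  he <- variation$herniation
  cs_on <- if (!is.null(cs)) planted(cs$prop) else rep(FALSE, n)
  rs_on <- if (!is.null(rs)) planted(rs$prop) else rep(FALSE, n)
  he_on <- if (!is.null(he)) planted(he$prop) else rep(FALSE, n)
  cs_val <- if (!is.null(cs)) draw(cs$range %||% c(7, 8.5), n)
  rs_hval <- if (!is.null(rs) && !is.null(rs$height_range %||% NULL))
    draw(rs$height_range, n)
  rs_aval <- if (!is.null(rs) && !is.null(rs$angle_range %||% NULL))
    draw(rs$angle_range, n)
  he_val <- if (!is.null(he)) draw(he$extent_range %||% c(4, 9), n)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    if ("lordosis_angle" %in% num_keys) sp$lordosis_angle <- num_draws$lordosis_angle[i]
    if ("disc_height" %in% num_keys)
      sp$disc_heights <- rep(num_draws$disc_height[i], sp$n_discs)
    if ("noise_sd" %in% num_keys) sp$noise_sd <- num_draws$noise_sd[i]
    for (ax in 1:3) {
      rk <- c("rotation_x", "rotation_y", "rotation_z")[ax]
      tk <- c("translation_x", "translation_y", "translation_z")[ax]
      if (rk %in% num_keys) sp$pose$rotation[ax] <- num_draws[[rk]][i]
      if (tk %in% num_keys) sp$pose$translation[ax] <- num_draws[[tk]][i]
    }
    if (cs_on[i]) {
      lvl <- match(cs$level %||% "L4/5", sp$disc_labels)
      sp$canal_diameter[lvl] <- cs_val[i]
    }
    if (rs_on[i]) {
      lvl <- match(rs$level %||% "L4/5", sp$disc_labels)
      side <- rs$side %||% "left"
      if (!is.null(rs_hval)) sp$recess_height[lvl, side] <- rs_hval[i]
      if (!is.null(rs_aval)) sp$recess_angle[lvl, side] <- rs_aval[i]
    }
    if (he_on[i]) {
      lvl <- he$level %||% "L4/5"
      sp$herniation <- c(sp$herniation,
                         stats::setNames(list(list(extent = he_val[i],
                                                   zone = he$zone %||% "A")), lvl))
    }
    sp$seed <- as.integer(seed + i)
    validate_phantom_spec(sp)
    ph <- generate_phantom(sp, intensity = intensity)
    ph$spec <- sp
    out[[i]] <- ph
  }
  out
}
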