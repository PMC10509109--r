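#' Generate a synthetic patient cohort
#'
#' Draws `n` digital phantoms whose 120 kVp ground-truth risk classes
#' follow the reference cohort's class mix (29.0 / 10.7 / 26.6 / 20.1 /
#' 13.6 % for classes 0, 1-10, 11-100, 101-400, >400) and whose BMI
#' follows a log-normal distribution matched to median 26.1 kg/m^2 with
#' IQR 23.7--28.3, truncated to the observed range [18.9, 39.9].
#'
#' For each subject a target class is drawn first; lesion sets (count, disc
#' areas and peak attenuations from class-specific log-normal
#' distributions) are then rejection-sampled until the noiseless 120 kVp
#' Agatston score of the rasterized phantom lands in the target class.
#' Lesions are placed uniformly at random, rejecting positions that leave
#' the grid, touch the aortic blood pool, or overlap another lesion. The
#' whole procedure is a deterministic function of `(n, seed)`.
#'
#' Cohort phantoms default to a 192 x 192 in-plane crop (2 slices) at the
#' standard 250/512 mm pixel spacing: Agatston arithmetic depends on pixel
#' size, not on matrix extent, and the crop keeps large simulation studies
#' cheap.
#'
#' @param n Number of subjects (>= 0).
#' @param seed Integer seed.
#' @param grid Phantom grid `(n_slices, n_rows, n_cols)`.
#' @param bmi_range Truncation range for the BMI draw (kg/m^2).
#' @return List of [patient_phantom()] objects; each carries its intended
#'   class in attribute `target_class`.
#' @export
generate_cohort <- function(n, seed = 1L, grid = c(2L, 192L, 192L),
                            bmi_range = c(18.9, 39.9)) {
  if (length(n) != 1L || !is.numeric(n) || n < 0)
    stop("`n` must be a non-negative integer", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)
  lapply(seq_len(n), function(i)
    .generate_subject(grid = as.integer(grid), bmi_range = bmi_range))
}

# class mix of the reference cohort (n = 169)
.class_probs <- c(49, 18, 45, 34, 23) / 169

# rounded-score intervals of the five classes (upper bound of the top class
# is just a sampling cap)
.class_ranges <- list(c(0, 0), c(1, 10), c(11, 100), c(101, 400), c(401, 1e5))

# per-class lesion-set distributions (classes 2..5): count = base + Poisson,
# disc areas and peak HU log-normal (HU at the 120 kVp reference)
.lesion_params <- list(
  `2` = list(n_base = 1, n_lambda = 0.25, area_meanlog = log(2.2),
             peak_meanlog = log(200)),
  `3` = list(n_base = 1, n_lambda = 2,    area_meanlog = log(3.0),
             peak_meanlog = log(260)),
  `4` = list(n_base = 2, n_lambda = 4,    area_meanlog = log(4.5),
             peak_meanlog = log(320)),
  `5` = list(n_base = 6, n_lambda = 6,    area_meanlog = log(6.0),
             peak_meanlog = log(420))
)
.area_sdlog <- 0.5
.peak_sdlog <- 0.35
.peak_clip <- c(140, 2000)

# BMI: log-normal matched to median 26.1, IQR [23.7, 28.3]
# sdlog = log(28.3/23.7) / (2 * qnorm(0.75))
.bmi_meanlog <- log(26.1)
.bmi_sdlog <- log(28.3 / 23.7) / (2 * stats::qnorm(0.75))

.draw_bmi <- function(range) {
  repeat {
    b <- stats::rlnorm(1, .bmi_meanlog, .bmi_sdlog)
    if (b >= range[1] && b <= range[2]) return(b)
  }
}

.generate_subject <- function(grid, bmi_range) {
  bmi <- .draw_bmi(bmi_range)
  cls <- sample.int(5L, 1L, prob = .class_probs)
  pool_center <- c(1, 40, 40)
  ph_args <- list(bmi = bmi, grid = grid, aortic_center = pool_center)
  if (cls == 1L) {
    ph <- do.call(patient_phantom, c(list(lesions = list()), ph_args))
    attr(ph, "target_class") <- risk_levels()[1]
    return(ph)
  }
  par <- .lesion_params[[as.character(cls)]]
  rng <- .class_ranges[[cls]]
  sp <- 250 / 512
  pool_r_px <- 25 / 2 / sp
  for (try in seq_len(2000L)) {
    n_les <- par$n_base + stats::rpois(1, par$n_lambda)
    areas <- stats::rlnorm(n_les, par$area_meanlog, .area_sdlog)
    peaks <- pmin(pmax(stats::rlnorm(n_les, par$peak_meanlog, .peak_sdlog),
                       .peak_clip[1]), .peak_clip[2])
    les <- .place_lesions(areas, peaks, grid, sp, pool_center, pool_r_px)
    if (is.null(les)) next
    ph <- do.call(patient_phantom, c(list(lesions = les), ph_args))
    s <- .round_half_up(ground_truth_score(ph)$total_score)
    if (s >= rng[1] && s <= rng[2]) {
      attr(ph, "target_class") <- risk_levels()[cls]
      return(ph)
    }
  }
  stop("failed to generate a subject in the target risk class", call. = FALSE)
}

.place_lesions <- function(areas, peaks, grid, sp, pool_center, pool_r_px) {
  ns <- grid[1]; nr <- grid[2]; nc <- grid[3]
  placed <- list()
  for (i in seq_along(areas)) {
    r_px <- sqrt(areas[i] / pi) / sp
    lo <- r_px + 2; hir <- nr - r_px - 1; hic <- nc - r_px - 1
    if (hir <= lo || hic <= lo) return(NULL)
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      slice <- sample.int(ns, 1L)
      ctr <- c(stats::runif(1, lo, hir), stats::runif(1, lo, hic))
      if (sqrt(sum((ctr - pool_center[2:3])^2)) < pool_r_px + r_px + 2) next
      clash <- FALSE
      for (p in placed) {
        if (p$slice != slice) next
        if (sqrt(sum((p$center - ctr)^2)) <
            p$r_px + r_px + 2) { clash <- TRUE; break }
      }
      if (clash) next
      placed[[length(placed) + 1L]] <-
        list(slice = slice, center = ctr, r_px = r_px,
             lesion = lesion_spec(slice, ctr, areas[i], peaks[i]))
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  lapply(placed, `[[`, "lesion")
}
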