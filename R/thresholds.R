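#' Agatston density-score thresholds for a tube voltage
#'
#' The Agatston algorithm assigns each calcified lesion a density score of
#' 1--4 from its peak attenuation, using four lower bounds in Hounsfield
#' units (HU). The classical bounds (130, 200, 300, 400 HU) are defined for
#' scans acquired at 120 kVp. Because the measured attenuation of calcium
#' rises as tube voltage falls, scans acquired at 80 or 70 kVp require
#' rescaled bounds; `threshold_table()` returns the voltage-adapted set.
#'
#' @param kvp Tube voltage in kilovolt-peak; one of 70, 80, 120.
#' @return An object of class `threshold_table`: a list with elements
#'   `kvp` and `bounds` (named numeric vector `t1`..`t4`, strictly
#'   increasing lower bounds for density scores 1--4).
#' @examples
#' threshold_table(120)$bounds  # 130 200 300 400
#' threshold_table(70)$bounds   # 207 319 478 637
#' @seealso [density_weight()], [score_volume()]
#' @export
threshold_table <- function(kvp) {
  kvp <- .check_kvp(kvp)
  bounds <- .kvp_thresholds[[as.character(kvp)]]
  structure(list(kvp = kvp, bounds = bounds), class = "threshold_table")
}

.kvp_thresholds <- list(
  `120` = c(t1 = 130, t2 = 200, t3 = 300, t4 = 400),
  `80`  = c(t1 = 177, t2 = 272, t3 = 409, t4 = 545),
  `70`  = c(t1 = 207, t2 = 319, t3 = 478, t4 = 637)
)

.supported_kvp <- c(70, 80, 120)

.check_kvp <- function(kvp) {
  if (length(kvp) != 1L || !is.numeric(kvp) || !(kvp %in% .supported_kvp))
    stop("unsupported tube voltage; supported kVp values are: ",
         paste(.supported_kvp, collapse = ", "), call. = FALSE)
  as.integer(kvp)
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf("Agatston thresholds at %d kVp (HU): %s\n", x$kvp,
              paste(sprintf("score %d >= %g", 1:4, x$bounds), collapse = ", ")))
  invisible(x)
}

#' Density score of a peak attenuation value
#'
#' Maps peak HU to the Agatston density weight: 0 below the lowest bound,
#' otherwise the number of bounds at or below the value (bounds are
#' inclusive lower limits, so e.g. 130--199 HU is weight 1 at 120 kVp).
#'
#' @param peak_hu Numeric vector of peak attenuation values (HU).
#' @param table A [threshold_table()].
#' @return Integer vector of weights in 0..4.
#' @examples
#' density_weight(c(129, 130, 250, 400), threshold_table(120)) # 0 1 2 4
#' @export
density_weight <- function(peak_hu, table) {
  stopifnot(inherits(table, "threshold_table"))
  findInterval(peak_hu, table$bounds)
}

#' kVp-dependent attenuation scale factors
#'
#' `calcium_scale()` is the multiplier applied to calcium attenuation when
#' moving from the 120 kVp reference to a lower tube voltage; it equals the
#' ratio of the voltage-adapted Agatston thresholds to the classical ones
#' (545/400 = 1.3625 at 80 kVp, 637/400 = 1.5925 at 70 kVp).
#' `tissue_scale()` is the analogous multiplier for soft tissue and blood,
#' derived from the aortic blood-pool signal measured at each voltage
#' (51.0/48.5 at 80 kVp, 53.1/48.5 at 70 kVp).
#'
#' @inheritParams threshold_table
#' @return A single numeric multiplier; 1 at 120 kVp.
#' @export
calcium_scale <- function(kvp) {
  kvp <- .check_kvp(kvp)
  c(`120` = 1, `80` = 1.3625, `70` = 1.5925)[[as.character(kvp)]]
}

#' @rdname calcium_scale
#' @export
tissue_scale <- function(kvp) {
  kvp <- .check_kvp(kvp)
  c(`120` = 1, `80` = 51.0 / 48.5, `70` = 53.1 / 48.5)[[as.character(kvp)]]
}
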