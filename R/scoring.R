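#' Risk-class labels for CAC scores
#'
#' The ordinal cardiovascular risk classes used for CAC-based
#' stratification: 0, 1-10, 11-100, 101-400, >400.
#'
#' @return Character vector of the five ordered class labels.
#' @export
risk_levels <- function() c("0", "1-10", "11-100", "101-400", ">400")

#' Risk class of a total CAC score
#'
#' The total score is rounded half-up to an integer and binned into the
#' five ordinal classes.
#'
#' @param total_score Numeric vector of non-negative total CAC scores.
#' @return Ordered factor with levels [risk_levels()].
#' @examples
#' risk_class(c(0, 42, 400.4, 400.6))  # "0" "11-100" "101-400" ">400"
#' @export
risk_class <- function(total_score) {
  if (any(total_score < 0)) stop("CAC scores must be >= 0", call. = FALSE)
  s <- .round_half_up(total_score)
  cls <- cut(s, breaks = c(-Inf, 0.5, 10.5, 100.5, 400.5, Inf),
             labels = risk_levels(), right = TRUE)
  factor(cls, levels = risk_levels(), ordered = TRUE)
}

# 8-connected labeling of the sparse suprathreshold pixel set of one slice.
# `idx` are linear indices into an (nr x nc) matrix; returns an integer
# membership vector parallel to idx. Components are found as the connected
# components of the pixel adjacency graph.
.label_components8 <- function(idx, nr, nc) {
  n <- length(idx)
  if (n <= 1L) return(rep(1L, n))
  present <- logical(nr * nc)
  present[idx] <- TRUE
  id <- integer(nr * nc)
  id[idx] <- seq_len(n)
  r <- ((idx - 1L) %% nr) + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  from <- integer(0); to <- integer(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    ok <- (r + dr >= 1L) & (r + dr <= nr)
    nbr <- idx[ok] + dr + dc * nr
    ok2 <- nbr >= 1L & nbr <= nr * nc
    src <- idx[ok][ok2]; nbr <- nbr[ok2]
    hit <- present[nbr]
    if (any(hit)) {
      from <- c(from, id[src[hit]])
      to <- c(to, id[nbr[hit]])
    }
  }
  if (!length(from)) return(seq_len(n))
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Detect calcified lesions in a volume
#'
#' Per slice, pixels at or above the lowest threshold of `table` are grouped
#' into 8-connected in-plane components; components whose area
#' (pixel count x pixel area) reaches `min_area` are retained as lesions.
#' The minimum-area rule eliminates isolated suprathreshold pixels caused by
#' noise. Each lesion's density weight comes from the maximum HU in the
#' component, and its score is weight x area. There is no cross-slice
#' merging: Agatston scoring sums per-slice contributions.
#'
#' @param volume An [image_volume()].
#' @param table A [threshold_table()].
#' @param min_area Minimum lesion area in mm^2 (default 1).
#' @return A data frame with one row per lesion: `slice`, `n_pixels`,
#'   `area_mm2`, `peak_hu`, `weight`, `score`, and a list column `pixels`
#'   of linear in-slice pixel indices.
#' @export
detect_lesions <- function(volume, table, min_area = 1.0) {
  stopifnot(inherits(volume, "image_volume"), inherits(table, "threshold_table"))
  if (is.null(volume$pixel_spacing) || !is.finite(volume$pixel_spacing))
    stop("volume lacks pixel spacing metadata", call. = FALSE)
  pa <- pixel_area(volume)
  t1 <- table$bounds[[1]]
  d <- dim(volume$voxels)
  out <- list()
  for (s in seq_len(d[3])) {
    slab <- volume$voxels[, , s]
    idx <- which(slab >= t1)
    if (!length(idx)) next
    memb <- .label_components8(idx, d[1], d[2])
    for (px in split(idx, memb)) {
      area <- length(px) * pa
      if (area < min_area) next
      peak <- max(slab[px])
      w <- density_weight(peak, table)
      out[[length(out) + 1L]] <-
        data.frame(slice = s, n_pixels = length(px), area_mm2 = area,
                   peak_hu = as.numeric(peak), weight = w, score = w * area,
                   pixels = I(list(px)))
    }
  }
  if (!length(out))
    return(data.frame(slice = integer(0), n_pixels = integer(0),
                      area_mm2 = numeric(0), peak_hu = numeric(0),
                      weight = integer(0), score = numeric(0),
                      pixels = I(list())))
  do.call(rbind, out)
}

#' Total Agatston score of a lesion set
#'
#' Sum over lesions of density weight x area (mm^2); an empty lesion set
#' scores 0.
#'
#' @param lesions A lesion data frame from [detect_lesions()].
#' @return Total score (unitless).
#' @export
agatston_score <- function(lesions) {
  if (is.null(lesions) || nrow(lesions) == 0) return(0)
  sum(lesions$weight * lesions$area_mm2)
}

#' Score a volume at a given tube voltage
#'
#' Composition of [threshold_table()], [detect_lesions()],
#' [agatston_score()] and [risk_class()]; the lesion table is kept in the
#' result for audit.
#'
#' @param volume An [image_volume()].
#' @param kvp Tube voltage the volume was acquired at (70, 80 or 120);
#'   selects the threshold set.
#' @param min_area Minimum lesion area in mm^2.
#' @return An object of class `cac_result`: list with `total_score`,
#'   `rounded_score`, `risk_class`, `kvp` and `lesions`.
#' @export
score_volume <- function(volume, kvp, min_area = 1.0) {
  tab <- threshold_table(kvp)
  lesions <- detect_lesions(volume, tab, min_area = min_area)
  total <- agatston_score(lesions)
  structure(list(total_score = total,
                 rounded_score = as.integer(.round_half_up(total)),
                 risk_class = risk_class(total),
                 kvp = tab$kvp, lesions = lesions),
            class = "cac_result")
}

#' @export
print.cac_result <- function(x, ...) {
  cat(sprintf("CAC score at %d kVp: %.1f (rounded %d), risk class %s, %d lesion(s)\n",
              x$kvp, x$total_score, x$rounded_score,
              as.character(x$risk_class), nrow(x$lesions)))
  invisible(x)
}
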