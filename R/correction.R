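#' Cohort mean size index
#'
#' The correction normalizes every animal to the average size of the analysis
#' cohort, so the reference is the arithmetic mean of the *animal-level* size
#' indices: an animal contributing two kidney rows is still counted once.
#'
#' @param records data.frame with `animal` and `size_index` columns (one size
#'   index per animal; duplicated rows per animal must agree).
#' @return list with `mean_size_index` and `n_animals`.
#' @export
cohort_mean_size_index <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(all(c("animal", "size_index") %in% names(records)))
  per_animal <- tapply(records$size_index, records$animal, function(v) {
    u <- unique(v)
    if (length(u) > 1L)
      stop("inconsistent size_index within an animal", call. = FALSE)
    u
  })
  per_animal <- as.numeric(per_animal)
  if (any(!is.finite(per_animal)) || any(per_animal <= 0))
    stop("size indices must be positive", call. = FALSE)
  list(mean_size_index = mean(per_animal), n_animals = length(per_animal))
}

#' Subject-size correction of cortical CT numbers
#'
#' Applies the closed-form beam-hardening correction
#' \deqn{corrected = measured + A \ln(size_i / \overline{size})}
#' where `A` is the pooled calibration slope and the reference is the cohort
#' mean size index. A kidney whose animal is exactly average-sized is left
#' unchanged; smaller-than-average animals (whose CT numbers are inflated by
#' the artifact) are adjusted downward, larger ones upward.
#'
#' @param measured_hu measured mean cortical HU (vectorized).
#' @param size_index the animal's size index (> 0, vectorized).
#' @param mean_size_index reference (cohort mean) size index, > 0; may also
#'   be the `CohortStats` list from [cohort_mean_size_index()].
#' @param A pooled calibration coefficient; may also be a `ct_calibration`,
#'   in which case its pooled A is used.
#' @return corrected HU, same length as `measured_hu`.
#' @export
#' @examples
#' correct_ct_number(50, 6, 4, A = 30)  # 50 + 30*log(1.5) = 62.16 HU
correct_ct_number <- function(measured_hu, size_index, mean_size_index, A) {
  if (inherits(A, "ct_calibration")) A <- A$pooled$A
  if (is.list(mean_size_index)) mean_size_index <- mean_size_index$mean_size_index
  stop_if_not_scalar_number(mean_size_index, "mean_size_index", positive = TRUE)
  stop_if_not_scalar_number(A, "A")
  if (any(!is.finite(size_index)) || any(size_index <= 0))
    stop("size_index must be positive", call. = FALSE)
  measured_hu + A * log(size_index / mean_size_index)
}

#' Correct a whole cohort table
#'
#' Fills the `corrected_hu` column of a cohort table from its `measured_hu`
#' and `size_index` columns, using the pooled calibration coefficient and (by
#' default) the cohort's own mean size index as reference. Supplying
#' `reference_size` instead fixes the normalization for cross-study
#' comparability.
#'
#' @param records cohort data.frame (see [read_cohort_table()]).
#' @param A pooled coefficient or a `ct_calibration`.
#' @param reference_size optional fixed reference size index.
#' @return `records` with `corrected_hu` filled; the reference used is stored
#'   in attribute `reference_size`.
#' @export
correct_cohort <- function(records, A, reference_size = NULL) {
  records <- as.data.frame(records)
  ref <- reference_size %||% cohort_mean_size_index(records)$mean_size_index
  records$corrected_hu <- correct_ct_number(records$measured_hu,
                                            records$size_index, ref, A)
  attr(records, "reference_size") <- ref
  records
}

#' Area-weighted prediction of the CT-number increase from fibrosis
#'
#' Motivates detectability: modelling fibrotic cortex as a volume mixture of
#' normal kidney tissue and collagen, the mean CT number of a kidney with
#' fibrosis volume fraction `f` is `(1-f)k + fc` where `k` and `c` are the
#' midpoints of the normal-kidney and collagen HU ranges. The percent
#' increase over a fibrosis-free kidney is `100 f (c - k) / k`, linear in
#' `f`. With the literature ranges (kidney 20-40 HU, tendon/collagen
#' 75-115 HU), 5% fibrosis by volume predicts a mean CT number about 10%
#' greater.
#'
#' @param fibrosis_fraction fibrosis volume fraction(s) in `[0, 1]`.
#' @param kidney_hu_range HU range of healthy renal tissue; default
#'   `c(20, 40)`.
#' @param collagen_hu_range HU range of collagen (tendon); default
#'   `c(75, 115)`.
#' @return predicted percent increase in mean CT number.
#' @export
#' @examples
#' predicted_ct_increase(0.05)  # ~10.8 percent
predicted_ct_increase <- function(fibrosis_fraction,
                                  kidney_hu_range = c(20, 40),
                                  collagen_hu_range = c(75, 115)) {
  if (any(!is.finite(fibrosis_fraction)) ||
      any(fibrosis_fraction < 0 | fibrosis_fraction > 1))
    stop("'fibrosis_fraction' must lie in [0, 1]", call. = FALSE)
  for (r in list(kidney_hu_range, collagen_hu_range))
    if (length(r) != 2L || r[1] > r[2])
      stop("HU ranges must be length-2 with lo <= hi", call. = FALSE)
  k <- mean(kidney_hu_range)
  cc <- mean(collagen_hu_range)
  if (k == 0) stop("kidney HU midpoint is zero; relative increase undefined",
                   call. = FALSE)
  100 * fibrosis_fraction * (cc - k) / k
}

#' Resolve unknown-side kidneys
#'
#' Some histology tissue arrives with unknown laterality; for those animals
#' one kidney scan is chosen at random (with a recorded seed) so each kidney
#' measurement is matched to one histology record. Known-side rows pass
#' through untouched.
#'
#' @param records cohort data.frame with `animal` and `side`
#'   (`"left"`/`"right"`/`"unknown"`).
#' @param seed RNG seed recorded in attribute `side_seed`.
#' @return records with at most one `unknown`-side row kept per animal.
#' @export
resolve_unknown_sides <- function(records, seed = 1L) {
  records <- as.data.frame(records)
  stopifnot(all(records$side %in% c("left", "right", "unknown")))
  with_seed(seed, {
    keep <- rep(TRUE, nrow(records))
    for (a in unique(records$animal)) {
      idx <- which(records$animal == a & records$side == "unknown")
      if (length(idx) > 1L) keep[setdiff(idx, sample(idx, 1L))] <- FALSE
    }
    out <- records[keep, , drop = FALSE]
    attr(out, "side_seed") <- seed
    out
  })
}

## ---- cohort table CSV io --------------------------------------------------

.cohort_columns <- c("animal", "side", "group", "measured_hu", "size_index",
                     "corrected_hu", "fibrosis_score", "blue_fraction", "bun")

#' Read / write the cohort table CSV
#'
#' The cohort table is the tabular exchange format of the pipeline: one row
#' per kidney, keyed by `(animal, side)`, with the fixed header
#' `animal, side, group, measured_hu, size_index, corrected_hu,
#' fibrosis_score, blue_fraction, bun`. `side` must be one of
#' `left`/`right`/`unknown`; fibrosis scores lie in `[0, 4]`; an animal
#' contributes at most two rows. Empty cells are `NA`.
#'
#' @param path CSV file path.
#' @return `read_cohort_table()`: validated data.frame;
#'   `write_cohort_table()`: `path`, invisibly.
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cohort_columns, names(tab))
  if (length(miss))
    stop("cohort table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_cohort_table(tab[.cohort_columns])
}

#' @rdname read_cohort_table
#' @param records cohort data.frame.
#' @export
write_cohort_table <- function(records, path) {
  records <- validate_cohort_table(as.data.frame(records))
  utils::write.csv(records[.cohort_columns], path, row.names = FALSE)
  invisible(path)
}

validate_cohort_table <- function(tab) {
  for (col in setdiff(.cohort_columns, names(tab))) tab[[col]] <- NA
  if (!all(tab$side %in% c("left", "right", "unknown")))
    stop("side must be left/right/unknown", call. = FALSE)
  sc <- tab$fibrosis_score
  if (any(!is.na(sc) & (sc < 0 | sc > 4)))
    stop("fibrosis_score must lie in [0, 4]", call. = FALSE)
  counts <- table(tab$animal)
  if (any(counts > 2L))
    stop("animal(s) with more than two kidney rows: ",
         paste(names(counts)[counts > 2L], collapse = ", "), call. = FALSE)
  tab
}
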