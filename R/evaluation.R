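#' Segmentation and sizing evaluation metrics
#'
#' Automatic results are scored against reference masks (manual labels in
#' the field, exact ground truth for synthetic scenes): the
#' pixel-difference error measures segmentation quality as the symmetric
#' difference between masks relative to the reference fruit area, and the
#' diameter errors are relative to the reference fruit's MD. Per-condition
#' tables report the minimum, average and maximum of each metric, since
#' the per-fruit errors follow no common distribution.
#'
#' @name evaluation
NULL

#' Pixel-difference error between automatic and reference masks
#'
#' `100 * |auto XOR reference| / |reference|`: the number of differing
#' pixels as a percentage of the reference foreground area. Note that a
#' manual reference contour of a high-resolution fruit is itself only
#' repeatable to about 3\% of the fruit area, which sets a floor on
#' meaningful differences.
#'
#' @param auto,reference binary matrices of equal dimensions; the
#'   reference must have nonempty foreground.
#' @return error percentage (>= 0; 0 iff the masks are identical).
#' @export
pixel_difference_error <- function(auto, reference) {
  a <- mask_to_logical(auto)
  r <- mask_to_logical(reference)
  if (!all(dim(a) == dim(r))) stop("masks must have identical dimensions")
  ref_area <- sum(r)
  if (ref_area == 0) stop("reference mask has no foreground pixels")
  100 * sum(xor(a, r)) / ref_area
}

#' Relative diameter errors against the reference MD
#'
#' Each of MD, MAL-F1 and MAL-F2 is compared with the maximum distance
#' between contour pixels of the reference (fully labeled) fruit:
#' `100 * |value - reference_md| / reference_md`.
#'
#' @param auto_estimate a `diameter_estimate`.
#' @param reference_md reference maximum distance in pixels (> 0).
#' @return named numeric vector `md_err_pct`, `mal_f1_err_pct`,
#'   `mal_f2_err_pct`.
#' @export
relative_diameter_errors <- function(auto_estimate, reference_md) {
  if (reference_md <= 0) stop("reference MD must be positive")
  vals <- c(auto_estimate$md, auto_estimate$mal_f1, auto_estimate$mal_f2)
  errs <- 100 * abs(vals - reference_md) / reference_md
  names(errs) <- c("md_err_pct", "mal_f1_err_pct", "mal_f2_err_pct")
  errs
}

#' Compare one automatic segmentation + sizing result with its reference
#'
#' @param auto_mask automatic single-fruit mask.
#' @param reference_mask reference mask of the same fruit (for occluded
#'   fruit, the reference of the appropriate comparison: complete fruit or
#'   its non-occluded part, as the experiment requires -- this function
#'   does not subtract occluders).
#' @param auto_estimate optional precomputed `diameter_estimate` for
#'   `auto_mask`; computed if missing.
#' @param reference_md optional reference MD in pixels; computed from
#'   `reference_mask`'s contour if missing.
#' @return one-row `data.frame` with `pixel_diff_pct`, `reference_area`,
#'   `auto_area`, `md_err_pct`, `mal_f1_err_pct`, `mal_f2_err_pct`.
#' @export
compare_segmentation <- function(auto_mask, reference_mask,
                                 auto_estimate = NULL, reference_md = NULL) {
  if (is.null(auto_estimate)) auto_estimate <- estimate_diameter(auto_mask)
  if (is.null(reference_md)) {
    reference_md <- max_pairwise_distance(extract_contour(reference_mask))
  }
  errs <- relative_diameter_errors(auto_estimate, reference_md)
  data.frame(pixel_diff_pct = pixel_difference_error(auto_mask, reference_mask),
             reference_area = sum(mask_to_logical(reference_mask)),
             auto_area = sum(mask_to_logical(auto_mask)),
             md_err_pct = unname(errs["md_err_pct"]),
             mal_f1_err_pct = unname(errs["mal_f1_err_pct"]),
             mal_f2_err_pct = unname(errs["mal_f2_err_pct"]))
}

#' Summarize comparisons for one experimental condition
#'
#' @param comparisons `data.frame` of rows from [compare_segmentation()]
#'   (or any data.frame of numeric metric columns), nonempty.
#' @param tag condition label, e.g. `"bright"`, `"low"`, `"occ_le_33"`.
#' @return `data.frame` with one row per metric and columns `condition`,
#'   `metric`, `min`, `average`, `max`.
#' @export
summarize_condition <- function(comparisons, tag) {
  comparisons <- as.data.frame(comparisons)
  if (nrow(comparisons) == 0) stop("cannot summarize an empty comparison set")
  num <- comparisons[vapply(comparisons, is.numeric, TRUE)]
  out <- do.call(rbind, lapply(names(num), function(nm) {
    v <- num[[nm]]
    data.frame(condition = tag, metric = nm, min = min(v),
               average = mean(v), max = max(v))
  }))
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as JSON and CSV
#'
#' @param comparisons per-fruit comparison rows.
#' @param summaries per-condition summary rows from [summarize_condition()].
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @export
write_evaluation_report <- function(comparisons, summaries,
                                    json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(fruits = comparisons, summaries = summaries),
                         json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(comparisons, csv_path, row.names = FALSE)
  }
  invisible(NULL)
}
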