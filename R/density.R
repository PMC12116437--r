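#' Aggregate raw counts into per-subject regional densities
#'
#' For each subject, region and slide, the two hemisphere counts are
#' pooled and divided by the pooled area (cells/mm^2); for regions
#' spanning multiple slides the mean of the slide densities is taken.
#' Midline (unilateral) records are allowed and use the single available
#' hemisphere. Subjects with no record for a region get an explicit
#' `NA`, never a silent zero.
#'
#' @param records Long-format count table with columns subject_id,
#'   group, litter_id, region, hemisphere, slide_index, count,
#'   area_mm2.
#' @return Object of class `density_table`: a data frame with
#'   subject_id, group, litter_id and one density column per region
#'   (region order follows first appearance in `records`).
#' @export
compute_density <- function(records) {
  required <- c("subject_id", "group", "litter_id", "region",
                "hemisphere", "slide_index", "count", "area_mm2")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("compute_density: missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(records$area_mm2 <= 0 | is.na(records$area_mm2)))
    stop("compute_density: nonpositive ROI area in rows ",
         paste(utils::head(which(records$area_mm2 <= 0 |
                                   is.na(records$area_mm2))), collapse = ", "))
  if (any(records$count < 0))
    stop("compute_density: negative counts present")
  key <- paste(records$subject_id, records$region, records$hemisphere,
               records$slide_index, sep = "\r")
  if (anyDuplicated(key))
    stop("compute_density: duplicate (subject, region, hemisphere, slide) ",
         "records, e.g. ",
         gsub("\r", "/", key[duplicated(key)][1]))

  slide_key <- paste(records$subject_id, records$region,
                     records$slide_index, sep = "\r")
  cnt <- tapply(records$count, slide_key, sum)
  ar <- tapply(records$area_mm2, slide_key, sum)
  slide_density <- cnt / ar
  sr_key <- sub("\r[^\r]*$", "", names(slide_density))
  dens <- tapply(slide_density, sr_key, mean)

  subjects <- unique(records$subject_id)
  regions <- unique(records$region)
  mat <- matrix(NA_real_, length(subjects), length(regions),
                dimnames = list(subjects, regions))
  parts <- strsplit(names(dens), "\r", fixed = TRUE)
  for (i in seq_along(dens)) {
    mat[parts[[i]][1], parts[[i]][2]] <- dens[[i]]
  }

  meta <- unique(records[, c("subject_id", "group", "litter_id")])
  if (anyDuplicated(meta$subject_id))
    stop("compute_density: inconsistent group/litter metadata for a subject")
  meta <- meta[match(subjects, meta$subject_id), ]
  out <- cbind(meta, as.data.frame(mat, optional = TRUE))
  rownames(out) <- NULL
  structure(out, regions = regions, class = c("density_table", "data.frame"))
}

#' Extract the numeric density matrix of a density table
#'
#' @param dens A `density_table`.
#' @param group Optional group label to subset rows.
#' @return Numeric matrix, subjects x regions, with subject rownames.
#' @export
density_matrix <- function(dens, group = NULL) {
  regions <- attr(dens, "regions")
  d <- as.data.frame(dens)
  if (!is.null(group)) {
    if (!any(d$group == group))
      stop("density_matrix: no subjects in group '", group, "'")
    d <- d[d$group == group, , drop = FALSE]
  }
  m <- as.matrix(d[, regions, drop = FALSE])
  rownames(m) <- d$subject_id
  m
}
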