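#' Per-subject volumetric measurements
#'
#' Holds one subject's total intracranial volume (TIV, mm^3) and regional
#' gray-matter volumes (rGM, mm^3, in atlas order).
#'
#' @param subject_id subject label.
#' @param tiv positive scalar, mm^3.
#' @param rgm positive numeric vector, one value per atlas region; their sum
#'   must not exceed `tiv`.
#' @param atlas optional [region_atlas()]; names `rgm` when supplied.
#' @return Object of class `subject_volumetrics`.
#' @export
subject_volumetrics <- function(subject_id, tiv, rgm, atlas = NULL) {
  if (!is.numeric(tiv) || length(tiv) != 1L || !is.finite(tiv) || tiv <= 0)
    stop_ctrl("tiv must be a single positive number")
  rgm_names <- names(rgm)
  rgm <- as.numeric(rgm)
  names(rgm) <- rgm_names
  if (any(!is.finite(rgm)) || any(rgm <= 0))
    stop_ctrl("rgm values must be positive and finite")
  if (!is.null(atlas)) {
    if (length(rgm) != nrow(atlas))
      stop_ctrl("rgm length ", length(rgm), " does not match atlas size ",
                nrow(atlas))
    names(rgm) <- atlas$region_name
  }
  if (sum(rgm) > tiv)
    stop_ctrl("sum of rgm (", format(sum(rgm)), ") exceeds tiv (",
              format(tiv), ") for subject ", subject_id)
  structure(list(subject_id = as.character(subject_id),
                 tiv = tiv, rgm = rgm),
            class = "subject_volumetrics")
}

#' Read per-subject volumetrics from delimited text
#'
#' Long format: columns `subject_id`, `region_name`, `rgm`, `tiv` (tiv
#' repeated within subject), tab- or comma-delimited with header.
#'
#' @param path file path.
#' @param atlas [region_atlas()] used to validate and order regions.
#' @return Named list of [subject_volumetrics()].
#' @export
read_volumetrics <- function(path, atlas) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "region_name", "rgm", "tiv")
  if (!all(need %in% names(df)))
    stop_ctrl("volumetrics file must have columns ",
              paste(need, collapse = ", "))
  out <- lapply(split(df, df$subject_id), function(d) {
    idx <- match(atlas$region_name, d$region_name)
    if (anyNA(idx))
      stop_ctrl("subject ", d$subject_id[1], " missing regions: ",
                paste(utils::head(atlas$region_name[is.na(idx)], 3),
                      collapse = ", "))
    subject_volumetrics(d$subject_id[1], d$tiv[1], d$rgm[idx], atlas)
  })
  out[order(names(out))]
}

#' Assemble the long-format study table
#'
#' Inner-joins control profiles and volumetrics on (subject, region) into
#' the observation table the mixed models consume: one row per subject and
#' region with columns `subject_id`, `region_name`, `ac`, `mc`, `strength`,
#' `rgm`, `tiv`. Subjects present in only one input are dropped with a
#' warning; rows with any missing value are dropped with a logged count.
#'
#' @param profiles list of `control_profile` (or one data.frame covering
#'   several subjects).
#' @param volumetrics list of [subject_volumetrics()].
#' @param atlas optional [region_atlas()]; defaults to the profile regions.
#' @return Object of class `study_table` (a data.frame); the scaled view is
#'   added later by [center_and_scale()].
#' @export
assemble <- function(profiles, volumetrics, atlas = NULL) {
  if (inherits(profiles, "data.frame")) profiles <- list(profiles)
  prof <- do.call(rbind, lapply(profiles, as.data.frame))
  vol <- do.call(rbind, lapply(volumetrics, function(v) {
    rn <- names(v$rgm)
    if (is.null(rn)) {
      if (is.null(atlas))
        stop_ctrl("rgm vectors are unnamed and no atlas was supplied")
      if (length(v$rgm) != nrow(atlas))
        stop_ctrl("rgm length does not match atlas for subject ",
                  v$subject_id)
      rn <- atlas$region_name
    }
    data.frame(subject_id = v$subject_id, region_name = rn,
               rgm = as.numeric(v$rgm), tiv = v$tiv,
               stringsAsFactors = FALSE)
  }))
  sp <- unique(prof$subject_id)
  sv <- unique(vol$subject_id)
  common <- intersect(sp, sv)
  if (length(common) == 0L)
    stop_ctrl("no subjects shared between profiles and volumetrics")
  dropped <- setdiff(union(sp, sv), common)
  if (length(dropped) > 0L)
    warn_ctrl("dropping ", length(dropped),
              " subject(s) present in only one input: ",
              paste(utils::head(dropped, 5), collapse = ", "))
  tab <- merge(prof, vol, by = c("subject_id", "region_name"),
               sort = FALSE)
  if (anyDuplicated(tab[, c("subject_id", "region_name")]))
    stop_ctrl("duplicate (subject, region) pairs after join")
  n0 <- nrow(tab)
  cc <- stats::complete.cases(tab)
  if (any(!cc)) {
    message("assemble: dropped ", sum(!cc), " incomplete row(s)")
    tab <- tab[cc, , drop = FALSE]
  }
  # deterministic row order regardless of input order
  tab <- tab[order(tab$subject_id, tab$region_name), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(atlas)) attr(tab, "atlas") <- atlas
  class(tab) <- c("study_table", "data.frame")
  tab
}

#' Within-subject centering and z-scaling
#'
#' Implements the variable transform of the mixed models: `ac`, `mc`,
#' `strength` and `rgm` are centered to mean zero within each subject and
#' then z-scaled. By default the z denominator is the pooled standard
#' deviation of the centered column across all rows (`scale_within =
#' FALSE`), which preserves between-subject differences in within-subject
#' dispersion and keeps interaction terms interpretable; `scale_within =
#' TRUE` divides by each subject's own SD instead. TIV, constant within
#' subject, is centered and scaled across subjects (within-subject
#' centering would annihilate it).
#'
#' Scaled columns `ac_z`, `mc_z`, `strength_z`, `rgm_z`, `tiv_z` are added;
#' scaling constants are recorded in `attr(, "scaling")`.
#'
#' @param tab a [assemble()]d `study_table`.
#' @param scale_within logical; see above.
#' @return The `study_table` with the scaled view populated.
#' @export
center_and_scale <- function(tab, scale_within = FALSE) {
  if (!inherits(tab, "study_table")) stop_ctrl("expected a study_table")
  counts <- table(tab$subject_id)
  if (any(counts < 2L))
    stop_ctrl("within-subject centering needs >= 2 regions per subject; ",
              "offending subject(s): ",
              paste(utils::head(names(counts)[counts < 2L], 5),
                    collapse = ", "))
  subj <- tab$subject_id
  scaling <- list(scale_within = scale_within)
  for (col in c("ac", "mc", "strength", "rgm")) {
    x <- tab[[col]]
    centered <- x - stats::ave(x, subj, FUN = mean)
    if (scale_within) {
      s <- stats::ave(centered, subj, FUN = stats::sd)
      if (any(s == 0))
        stop_ctrl("zero within-subject variance in column '", col, "'")
      z <- centered / s
      scaling[[col]] <- list(method = "within_sd")
    } else {
      s <- stats::sd(centered)
      if (!is.finite(s) || s == 0)
        stop_ctrl("zero pooled variance in column '", col, "'")
      z <- centered / s
      scaling[[col]] <- list(method = "pooled_sd", sd = s)
    }
    tab[[paste0(col, "_z")]] <- z
  }
  per_subj <- tapply(tab$tiv, subj, function(v) v[1])
  mu <- mean(per_subj)
  s <- stats::sd(per_subj)
  if (!is.finite(s) || s == 0)
    stop_ctrl("zero pooled variance in column 'tiv'")
  tab$tiv_z <- (tab$tiv - mu) / s
  scaling$tiv <- list(method = "across_subjects", mean = mu, sd = s)
  attr(tab, "scaling") <- scaling
  tab
}

has_scaled_view <- function(tab) {
  all(c("ac_z", "mc_z", "strength_z", "rgm_z", "tiv_z") %in% names(tab))
}

#' Write a study table with a JSON scaling sidecar
#'
#' @param tab a `study_table`.
#' @param path TSV output path; the sidecar goes to `<path>.scaling.json`.
#' @export
write_study_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc <- attr(tab, "scaling")
  if (!is.null(sc))
    jsonlite::write_json(sc, paste0(path, ".scaling.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
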