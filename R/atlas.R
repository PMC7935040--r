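#' Region atlas
#'
#' A region atlas binds the rows/columns of every connectivity matrix to
#' named brain regions. Internally regions are indexed 0..n-1 in file order;
#' names must be unique. The package ships a 120-region default whose labels
#' follow the AAL2 naming convention (bilateral cortical, subcortical and
#' cerebellar structures plus midline vermis segments, no brain stem).
#'
#' @param region_name character vector of unique region labels.
#' @param hemisphere optional character vector in `c("left","right","none")`;
#'   inferred from `_L`/`_R` suffixes when missing.
#' @return An object of class `region_atlas`: a data.frame with columns
#'   `region_id` (0-based integer), `region_name`, `hemisphere`.
#' @examples
#' atl <- region_atlas(c("A_L", "A_R", "Vermis"))
#' nrow(atl)
#' @export
region_atlas <- function(region_name, hemisphere = NULL) {
  region_name <- as.character(region_name)
  if (length(region_name) < 1L) stop_ctrl("atlas needs at least one region")
  if (anyDuplicated(region_name))
    stop_ctrl("atlas region names must be unique")
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(grepl("_L$", region_name), "left",
                         ifelse(grepl("_R$", region_name), "right", "none"))
  }
  hemisphere <- match.arg(as.character(hemisphere),
                          c("left", "right", "none"), several.ok = TRUE)
  if (length(hemisphere) != length(region_name))
    stop_ctrl("hemisphere must match region_name in length")
  out <- data.frame(region_id = seq_along(region_name) - 1L,
                    region_name = region_name,
                    hemisphere = hemisphere,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_atlas", "data.frame")
  out
}

#' Read a region atlas from delimited text
#'
#' Expects at least two columns (`region_id`, `region_name`), tab- or
#' comma-delimited, with an optional `hemisphere` column. `region_id` must be
#' contiguous 0..n-1 (or 1..n, which is shifted down).
#'
#' @param path path to the atlas file.
#' @return A [region_atlas()].
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop_ctrl("atlas file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("region_id", "region_name") %in% names(df)))
    stop_ctrl("atlas file must have columns region_id and region_name")
  ids <- as.integer(df$region_id)
  if (identical(sort(ids), seq_len(nrow(df)))) ids <- ids - 1L
  if (!identical(sort(ids), seq_len(nrow(df)) - 1L))
    stop_ctrl("region_id must be contiguous 0..n-1")
  df <- df[order(ids), , drop = FALSE]
  region_atlas(df$region_name,
               if ("hemisphere" %in% names(df)) df$hemisphere else NULL)
}

#' Default 120-region atlas
#'
#' @return The packaged 120-region atlas (AAL2 naming convention).
#' @export
default_atlas <- function() {
  read_atlas(system.file("extdata", "aal2_regions.tsv",
                         package = "connectrl", mustWork = TRUE))
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", nrow(x), " regions (",
      sum(x$hemisphere == "left"), "L/", sum(x$hemisphere == "right"), "R/",
      sum(x$hemisphere == "none"), " midline)\n", sep = "")
  invisible(x)
}
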