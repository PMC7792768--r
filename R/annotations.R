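#' Point annotations of nuclei centres
#'
#' Annotations (and decoded detections) are plain data frames with columns
#' `x`, `y` (0-based pixel coordinates, `x` = column, `y` = row) and `class`
#' (`"pos"` for Ki67+ / DAB-brown nuclei, `"neg"` for Ki67- / hematoxylin-
#' blue nuclei). These helpers construct, validate and round-trip them
#' through the CSV dialect `x,y,class`.
#'
#' @param x,y Numeric vectors of pixel coordinates (0-based).
#' @param class Character vector of class labels, `"pos"` or `"neg"`.
#' @return A data frame with columns `x`, `y`, `class`.
#' @examples
#' ann <- annotation_df(c(10, 40), c(12, 30), c("pos", "neg"))
#' tmp <- tempfile(fileext = ".csv")
#' write_annotations(ann, tmp)
#' identical(read_annotations(tmp), ann)
#' @export
annotation_df <- function(x = numeric(), y = numeric(), class = character()) {
  stopifnot(length(x) == length(y), length(x) == length(class))
  class <- as.character(class)
  if (length(class) && !all(class %in% c("pos", "neg"))) {
    stop_ki67("annotation class labels must be 'pos' or 'neg'",
              class = "ki67pi_contract_error")
  }
  data.frame(x = as.numeric(x), y = as.numeric(y), class = class,
             stringsAsFactors = FALSE)
}

#' @rdname annotation_df
#' @param ann An annotation data frame.
#' @param path Path of the CSV file.
#' @export
write_annotations <- function(ann, path) {
  ann <- annotation_df(ann$x, ann$y, ann$class)
  write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname annotation_df
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("numeric", "numeric", "character"))
  if (!identical(names(df), c("x", "y", "class"))) {
    stop_ki67("annotation file '%s' must have header x,y,class", path,
              class = "ki67pi_io_error")
  }
  annotation_df(df$x, df$y, df$class)
}
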