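#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows distinct n row_number across
#'   if_else case_when pull rename count first last lag lead
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pbinom pnorm pchisq rnbinom rbinom rpois rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Tabular outputs carry a single '#'-prefixed header line so downstream tools
# can treat them as commented TSV.
write_tsv_hash <- function(x, path) {
  header <- paste0("#", paste(names(x), collapse = "\t"))
  body <- do.call(paste, c(lapply(x, format_tsv_col), list(sep = "\t")))
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

format_tsv_col <- function(v) {
  if (is.double(v)) {
    out <- vapply(v, function(z) {
      if (is.na(z)) "NA" else format(z, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
    return(out)
  }
  out <- as.character(v)
  out[is.na(out)] <- "NA"
  out
}

read_tsv_hash <- function(path, col_types = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    nm <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
    out <- readr::read_tsv(path, skip = 1L, col_names = nm,
                           col_types = col_types %||% readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  } else {
    out <- readr::read_tsv(path, col_types = col_types %||% readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  }
  as_tibble(out)
}

stopf <- function(fmt, ..., class = "germpanel_error") {
  abort(sprintf(fmt, ...), class = class)
}

# once-per-session logging state (e.g. unknown chromosomes)
.germpanel_state <- new.env(parent = emptyenv())
.germpanel_state$warned_chroms <- character(0)
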