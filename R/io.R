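#' List-mode file I/O
#'
#' Columnar little-endian binary list-mode with a plain-text header.  The
#' header records the format version, the record type (singles or
#' coincidences), the column names, the record count, per-truth-class
#' tallies when a `truth` column is present, and any extra metadata (seed,
#' scenario digest, physics constants) passed as `meta`.  Doubles are
#' written column by column, so a write/read round trip is bit-exact.
#'
#' @param x singles or coincidences table (data.frame/data.table)
#' @param path output file
#' @param meta named list of additional header fields
#' @return `read_listmode` returns the table with the header attached as
#'   attribute `header`
#' @export
write_listmode <- function(x, path, meta = list()) {
  x <- as.data.table(x)
  truth_chr <- NULL
  if ("truth" %in% names(x)) {
    truth_chr <- x$truth
    x <- copy(x)
    x[, "truth" := match(truth_chr, c("true", "scatter", "random"))]
  }
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("list-mode columns must be numeric")
  }
  hdr <- c(
    "monopet-listmode 1",
    paste0("n_records: ", nrow(x)),
    paste0("columns: ", paste(names(x), collapse = " "))
  )
  if (!is.null(truth_chr)) {
    hdr <- c(hdr,
             paste0("count_true: ", sum(truth_chr == "true")),
             paste0("count_scatter: ", sum(truth_chr == "scatter")),
             paste0("count_random: ", sum(truth_chr == "random")))
  }
  for (k in names(meta)) {
    hdr <- c(hdr, paste0("meta_", k, ": ", paste(meta[[k]], collapse = " ")))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, "---"), con)
  for (j in seq_along(x)) {
    writeBin(as.numeric(x[[j]]), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated header: no '---' terminator")
    if (line == "---") break
    hdr <- c(hdr, line)
  }
  if (!length(hdr) || !startsWith(hdr[1], "monopet-listmode")) {
    stop("not a monopet list-mode file")
  }
  version <- strsplit(hdr[1], " ")[[1]][2]
  if (version != "1") stop("unsupported list-mode version: ", version)
  fields <- parse_header(hdr[-1])
  n <- as.integer(fields$n_records)
  cols <- strsplit(fields$columns, " ")[[1]]
  out <- vector("list", length(cols))
  names(out) <- cols
  for (j in seq_along(cols)) {
    v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    if (length(v) < n) {
      stop(sprintf(
        "truncated file: column '%s' ends at record %d of %d",
        cols[j], length(v), n))
    }
    out[[j]] <- v
  }
  dt <- as.data.table(out)
  if ("truth" %in% cols) {
    code <- dt$truth
    dt[, "truth" := c("true", "scatter", "random")[code]]
    tallies <- c(true = sum(code == 1), scatter = sum(code == 2),
                 random = sum(code == 3))
    for (cls in names(tallies)) {
      key <- paste0("count_", cls)
      if (!is.null(fields[[key]]) &&
          as.integer(fields[[key]]) != tallies[[cls]]) {
        stop("header truth-class counts disagree with the records")
      }
    }
  }
  if ("t_ns" %in% cols && is.unsorted(dt$t_ns)) {
    stop("list-mode records are not time-ordered")
  }
  if ("t1" %in% cols && is.unsorted(dt$t1)) {
    stop("list-mode records are not time-ordered")
  }
  attr(dt, "header") <- fields
  dt
}

parse_header <- function(lines) {
  out <- list()
  for (l in lines) {
    sep <- regexpr(": ", l, fixed = TRUE)
    if (sep < 0) stop("malformed header line: ", l)
    out[[substr(l, 1, sep - 1)]] <- substr(l, sep + 2, nchar(l))
  }
  out
}
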