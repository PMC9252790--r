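#' Read known transcription-factor binding sites from BED files
#'
#' BED3+ with the TF name in column 4 and, optionally, further columns
#' (ignored). BED coordinates are 0-based half-open; queries are made with
#' 1-based positions and converted in one place. Records with
#' `start >= end` are rejected with a warning. Note that ChIP-seq-derived
#' sites are typically regions of several hundred bases within which the
#' precise binding location is unknown; an overlap therefore only means the
#' variant falls inside such a region.
#'
#' @param paths Character vector of BED paths. Names are used as source
#'   labels (e.g. `c(ENCODE = "a.bed", custom = "b.bed")`); unnamed paths get
#'   the label `"custom"`.
#' @return An object of class `"known_sites"` wrapping a tibble (`chrom`,
#'   `start`, `end`, `tf_name`, `source`) and a prebuilt interval index.
#' @export
read_known_sites <- function(paths) {
  labels <- names(paths)
  if (is.null(labels)) labels <- rep("custom", length(paths))
  labels[!nzchar(labels)] <- "custom"
  tabs <- lapply(seq_along(paths), function(i) {
    tab <- utils::read.table(paths[[i]], sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) {
      stop(sprintf("%s: known-TFBS BED needs at least 4 columns (chrom, start, end, TF name)",
                   paths[[i]]), call. = FALSE)
    }
    out <- tibble::tibble(chrom = as.character(tab[[1L]]),
                          start = as.integer(tab[[2L]]),
                          end = as.integer(tab[[3L]]),
                          tf_name = as.character(tab[[4L]]),
                          source = labels[i])
    bad <- out$start >= out$end
    if (any(bad)) {
      warning(sprintf("%s: %d record(s) with start >= end rejected",
                      paths[[i]], sum(bad)))
      out <- out[!bad, ]
    }
    out
  })
  known_sites(dplyr::bind_rows(tabs))
}

#' @rdname read_known_sites
#' @param sites Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `tf_name`, `source`.
#' @export
known_sites <- function(sites) {
  stopifnot(all(c("chrom", "start", "end", "tf_name", "source") %in% names(sites)))
  if (any(!nzchar(sites$tf_name))) {
    stop("tf_name must be non-empty", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = norm_chrom(sites$chrom),
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end)
  )
  structure(list(sites = tibble::as_tibble(sites), gr = gr),
            class = "known_sites")
}

#' @export
print.known_sites <- function(x, ...) {
  cat(sprintf("<known_sites> %d interval(s), %d TF(s), sources: %s\n",
              nrow(x$sites), length(unique(x$sites$tf_name)),
              paste(unique(x$sites$source), collapse = ", ")))
  invisible(x)
}

#' Query known sites at a genomic position
#'
#' @param x A `"known_sites"` object.
#' @param chrom Chromosome name (`"chr1"` and `"1"` are equivalent).
#' @param pos 1-based position.
#' @return The tibble rows of all sites overlapping the position.
#' @export
query_known_sites <- function(x, chrom, pos) {
  stopifnot(inherits(x, "known_sites"))
  q <- GenomicRanges::GRanges(norm_chrom(chrom),
                              IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, x$gr)
  x$sites[S4Vectors::subjectHits(hits), ]
}

#' Read a gene-coordinate table
#'
#' Accepts BED6 (`chrom start end name score strand`, 0-based half-open) or
#' a TSV with header columns `chrom`, `start`, `end`, `name` and optional
#' `strand` (taken as 1-based inclusive and converted). Used by the
#' candidate-gene filter.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), `name`,
#'   `strand` (`"+"`/`"-"`, `"+"` when absent).
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("chrom", first, ignore.case = TRUE)) {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(tab) <- tolower(names(tab))
    stopifnot(all(c("chrom", "start", "end", "name") %in% names(tab)))
    tibble::tibble(chrom = as.character(tab$chrom),
                   start = as.integer(tab$start) - 1L,
                   end = as.integer(tab$end),
                   name = as.character(tab$name),
                   strand = if ("strand" %in% names(tab)) as.character(tab$strand) else "+")
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop("gene BED needs at least 4 columns", call. = FALSE)
    tibble::tibble(chrom = as.character(tab[[1L]]),
                   start = as.integer(tab[[2L]]),
                   end = as.integer(tab[[3L]]),
                   name = as.character(tab[[4L]]),
                   strand = if (ncol(tab) >= 6L) as.character(tab[[6L]]) else "+")
  }
}

#' Write intervals as BED
#'
#' @param sites Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   optional `tf_name`/`name` and `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  name <- if ("tf_name" %in% names(sites)) sites$tf_name
          else if ("name" %in% names(sites)) sites$name else "."
  strand <- if ("strand" %in% names(sites)) sites$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   sites$chrom, sites$start, sites$end, name, strand)
  writeLines(lines, path)
  invisible(path)
}
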