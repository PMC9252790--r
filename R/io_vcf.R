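#' Read variants from a VCF file
#'
#' Reads VCF 4.x (plain or gzipped), expands multi-allelic records into one
#' variant per ALT allele, and carries per-record depth, genotype and
#' allele-frequency annotations when present. Symbolic and structural ALT
#' alleles (`<DEL>`, breakends, `*`) are skipped with a warning. Analyses
#' are capped: a file with more records than `max_variants` is an error.
#'
#' @param path Path to the VCF file.
#' @param max_variants Record cap (default 10 000).
#' @param af_field INFO key holding the (user-supplied) allele frequency used
#'   by the rarity filter; default `"AF"`. Comma-separated per-ALT values are
#'   split alongside the alleles.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `depth`
#'   (INFO/DP), `genotype` (first sample GT string, `NA` if absent),
#'   `homozygous` (genotype is homozygous for this ALT), `af`, `line` (line
#'   number in the file).
#' @export
read_vcf <- function(path, max_variants = 10000L, af_field = "AF") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec > max_variants) {
    stop(sprintf("VCF contains %d variant records; analyses are limited to %s variants",
                 n_rec, format(max_variants, big.mark = " ")), call. = FALSE)
  }
  n_meta <- length(vcf@meta)
  has_gt <- ncol(vcf@gt) >= 2L
  info <- fix[, "INFO"]
  info_field <- function(rec_info, key) {
    m <- regmatches(rec_info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), rec_info))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }
  out <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    line_no <- n_meta + 1L + r
    pos <- suppressWarnings(as.integer(fix[r, "POS"]))
    ref <- toupper(fix[r, "REF"])
    alt_raw <- fix[r, "ALT"]
    if (is.na(pos) || pos < 1L || is.na(ref) || !grepl("^[ACGTN]+$", ref) ||
        is.na(alt_raw) || !nzchar(alt_raw)) {
      stop(sprintf("malformed VCF record at line %d of %s", line_no, path),
           call. = FALSE)
    }
    alts <- strsplit(alt_raw, ",", fixed = TRUE)[[1L]]
    afs <- strsplit(info_field(info[r], af_field), ",", fixed = TRUE)[[1L]]
    depth <- suppressWarnings(as.integer(info_field(info[r], "DP")))
    gt <- NA_character_
    if (has_gt) {
      fmt <- strsplit(vcf@gt[r, 1L], ":", fixed = TRUE)[[1L]]
      smp <- strsplit(vcf@gt[r, 2L], ":", fixed = TRUE)[[1L]]
      gi <- match("GT", fmt)
      if (!is.na(gi) && gi <= length(smp)) gt <- smp[gi]
      if (is.na(depth)) {
        di <- match("DP", fmt)
        if (!is.na(di) && di <= length(smp)) {
          depth <- suppressWarnings(as.integer(smp[di]))
        }
      }
    }
    rows <- vector("list", length(alts))
    for (a in seq_along(alts)) {
      alt <- toupper(alts[a])
      if (grepl("^<.*>$", alt) || grepl("[\\[\\]]", alt) || alt == "*" ||
          !grepl("^[ACGTN]+$", alt)) {
        warning(sprintf("skipping symbolic/structural ALT '%s' at line %d",
                        alt, line_no))
        next
      }
      af <- if (a <= length(afs)) suppressWarnings(as.numeric(afs[a])) else NA_real_
      hom <- if (is.na(gt)) NA else {
        al <- strsplit(gt, "[/|]")[[1L]]
        length(al) >= 2L && all(al == as.character(a))
      }
      rows[[a]] <- tibble::tibble(
        chrom = fix[r, "CHROM"], pos = pos, ref = ref, alt = alt,
        depth = depth, genotype = gt, homozygous = hom, af = af,
        line = line_no)
    }
    out[[r]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Write a minimal VCF file
#'
#' Emits a VCF 4.2 file from a variant tibble; used by the fixture
#' generators and the demo. Optional columns `depth`, `genotype` and `af`
#' become INFO/DP, the sample GT and INFO/AF.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` and optional
#'   annotation columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  has_gt <- "genotype" %in% names(variants) && any(!is.na(variants$genotype))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) cols <- c(cols, "FORMAT", "sample1")
  get_col <- function(v, col) {
    if (col %in% names(v)) v[[col]] else NA
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    info <- character(0)
    depth <- get_col(v, "depth")
    af <- get_col(v, "af")
    if (!is.na(depth)) info <- c(info, sprintf("DP=%d", as.integer(depth)))
    if (!is.na(af)) info <- c(info, sprintf("AF=%g", af))
    fields <- c(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                if (length(info)) paste(info, collapse = ";") else ".")
    if (has_gt) {
      gt <- get_col(v, "genotype")
      fields <- c(fields, "GT", if (is.na(gt)) "./." else gt)
    }
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}
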