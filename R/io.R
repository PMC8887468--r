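# BED (0-based half-open) <-> GRanges (1-based closed) readers/writers.

#' Read a BED file into GRanges
#'
#' Accepts 3-6 column BED; the name column (if present) becomes the range
#' names. BED's 0-based half-open coordinates are converted to the 1-based
#' closed convention used internally.
#'
#' @param path BED file.
#' @return \code{GRanges}.
#' @export
readBed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    dt[[1]], IRanges::IRanges(dt[[2]] + 1L, dt[[3]]),
    strand = if (ncol(dt) >= 6) dt[[6]] else "*"
  )
  if (ncol(dt) >= 4) names(gr) <- dt[[4]]
  gr
}

#' Write GRanges as BED
#'
#' @param gr \code{GRanges}.
#' @param path output path.
#' @param names optional name column (defaults to \code{names(gr)} or ".").
#' @export
writeBed <- function(gr, path, names = NULL) {
  if (is.null(names)) names <- if (!is.null(base::names(gr))) base::names(gr) else "."
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = names
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path two-column (chrom, length) TSV.
#' @return named numeric vector.
#' @export
readChromSizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  setNames(as.numeric(dt[[2]]), dt[[1]])
}

#' Read a gene-level count matrix
#'
#' @param path TSV with a gene-id first column and one column per sample.
#' @return integer matrix with gene rownames.
#' @export
readCountMatrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Write a QuantMatrix as TSV with header metadata
#'
#' Emits \code{#valueKind} and \code{#librarySizes} comment lines followed
#' by the window coordinates and per-sample values.
#'
#' @param qm \linkS4class{QuantMatrix}.
#' @param path output path.
#' @export
writeQuantMatrix <- function(qm, path) {
  hdr <- sprintf("#valueKind=%s", valueKind(qm))
  ls <- librarySizes(qm)
  if (!is.null(ls) && length(ls) && !all(is.na(ls))) {
    hdr <- c(hdr, sprintf("#librarySizes=%s",
                          paste(sprintf("%s:%g", names(ls), ls), collapse = ",")))
  }
  writeLines(hdr, path)
  w <- SummarizedExperiment::rowRanges(qm)
  dt <- data.table::data.table(
    id = names(w),
    chrom = as.character(GenomeInfoDb::seqnames(w)),
    start = GenomicRanges::start(w), end = GenomicRanges::end(w),
    quantValues(qm)
  )
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}
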