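#' Assembly pipeline parameters
#'
#' All stage parameters with their defaults: HPC k-mer length k = 16,
#' k-mer occurrence cap 500, candidate coverage threshold 300 bp, top 500
#' candidates per query, 800 bp chaining windows, z-mer length 10,
#' repeat-depth weighting over depths 10-100, dynamic alignment band
#' 50-3200 with 800 bp end extension; layout dovetail slack 100, near-best
#' ratio 0.95, unitig redundancy fraction 0.40. Every value can be
#' overridden by name.
#'
#' @param ... name = value overrides of any default.
#' @return a named parameter list.
#' @examples
#' pipelineConfig(k = 14L, maxCandidates = 100L)$k
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    # overlap / index
    k = 16L, maxKmerCount = 500L, subsampleDenominator = 4L,
    minCandidateCoverage = 300, maxCandidates = 500L,
    windowSize = 800L, minWindowMatch = 200, minChainTotal = 300,
    zmerLength = 10L, lowDepth = 10L, highDepth = 100L,
    bandMin = 50L, bandMax = 3200L, endBand = 800L,
    match = 2L, mismatch = -4L, gapOpen = 4L, gapExtend = 2L,
    minOverlapIdentity = 0.65,
    # trimming
    clipMinDepth = 2L, spurMargin = 50L, spurMinReads = 3L,
    minClippedSpan = 300L,
    # layout
    laySlack = 100L, layRatio = 0.95, layRedundancy = 0.40,
    extendTerminalReads = TRUE,
    # consensus
    cnsBand = 800L, cnsMinIdentity = 0.5, cnsRounds = 2L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  modifyList(cfg, over)
}

#' Run the full assembly pipeline
#'
#' overlap -> trim -> layout -> consensus, with stage outputs written next
#' to `outPrefix` (`.paf.tsv`, `.trim.tsv`, `.clip.paf.tsv`, `.lay.tsv`,
#' `.fa`). A stage is skipped when its output exists and is newer than its
#' inputs, unless `force = TRUE`; a structured message per stage reports
#' parameters and counts.
#'
#' @param input reads file (FASTA/FASTQ, optionally gzipped) or a
#'   `DNAStringSet`.
#' @param outPrefix path prefix for stage outputs.
#' @param params parameter list from [pipelineConfig()].
#' @param force rerun all stages regardless of timestamps.
#' @param verbose per-stage progress messages (default TRUE).
#' @return invisibly, a list with `contigs` (`DNAStringSet`), the stage
#'   file paths, and `executed` (names of stages actually run).
#' @export
runPipeline <- function(input, outPrefix, params = pipelineConfig(),
                        force = FALSE, verbose = TRUE) {
  if (is.character(input) && !file.exists(input))
    stop("input not found: ", input)
  files <- list(paf = paste0(outPrefix, ".paf.tsv"),
                trim = paste0(outPrefix, ".trim.tsv"),
                clip = paste0(outPrefix, ".clip.paf.tsv"),
                lay = paste0(outPrefix, ".lay.tsv"),
                fa = paste0(outPrefix, ".fa"))
  reads <- if (is.character(input)) readSequences(input) else
    as(input, "DNAStringSet")
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads) - 1L)
  inputTime <- if (is.character(input)) file.mtime(input) else Sys.time() - 1
  executed <- character(0)
  say <- function(...) if (verbose) message("[lrasm] ", ...)

  fresh <- function(out, dep) {
    file.exists(out) && file.mtime(out) >= dep
  }
  # overlap
  if (force || !fresh(files$paf, inputTime)) {
    say("overlap: ", length(reads), " reads (k=", params$k,
        ", K=", params$maxKmerCount, ", d=", params$minCandidateCoverage,
        ", A=", params$maxCandidates, ")")
    ov <- overlapReads(reads, params)
    writeOverlaps(ov, files$paf)
    executed <- c(executed, "overlap")
    say("overlap: ", nrow(ov@records), " overlaps")
  } else {
    say("overlap: up to date, skipped")
    ov <- readOverlaps(files$paf, names(reads), width(reads))
  }
  # trim
  if (force || !fresh(files$trim, file.mtime(files$paf))) {
    tr <- trimReads(reads, ov, params)
    writeTrim(tr$trim, files$trim)
    writeOverlaps(tr$overlaps, files$clip)
    executed <- c(executed, "trim")
    say("trim: ", sum(!is.na(tr$trim$keptStart)), " reads kept, ",
        sum(tr$trim$chimeric), " chimeric")
  } else {
    say("trim: up to date, skipped")
    tr <- list(trim = readTrim(files$trim),
               overlaps = readOverlaps(files$clip, names(reads),
                                       width(reads)))
  }
  # layout
  if (force || !fresh(files$lay, file.mtime(files$trim))) {
    lay <- layoutReads(tr$overlaps, tr$trim, params)
    writeLayout(lay, files$lay)
    executed <- c(executed, "layout")
    say("layout: ", length(lay@unitigs), " unitigs (w=", params$laySlack,
        ", r=", params$layRatio, ")")
  } else {
    say("layout: up to date, skipped")
    lay <- readLayout(files$lay, names(reads), width(reads))
  }
  # consensus
  if (force || !fresh(files$fa, file.mtime(files$lay))) {
    contigs <- consensusContigs(lay, reads, params)
    writeContigs(contigs, files$fa)
    executed <- c(executed, "consensus")
    say("consensus: ", length(contigs), " contigs, total ",
        sum(width(contigs)), " bp")
  } else {
    say("consensus: up to date, skipped")
    contigs <- readSequences(files$fa)
  }
  invisible(list(contigs = contigs, files = files, executed = executed))
}

writeTrim <- function(trim, path) {
  write.table(trim, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTrim <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Assembly contiguity statistics
#'
#' Total length, contig count, largest contig, N50 (length of the
#' shortest contig in the minimal set covering half the assembly) and L50
#' (size of that set). With a reference, contigs are mapped back
#' ([mapToReference()]) and covered fraction and alignment identity are
#' added.
#'
#' @param contigs `DNAStringSet` or character vector.
#' @param reference optional character(1) reference sequence.
#' @param params parameter list for reference mapping.
#' @return named list of statistics.
#' @export
assemblyStats <- function(contigs, reference = NULL,
                          params = pipelineConfig()) {
  lens <- if (is(contigs, "DNAStringSet")) width(contigs) else
    nchar(as.character(contigs))
  if (length(lens) == 0L)
    return(list(totalLength = 0L, nContigs = 0L, largest = 0L,
                n50 = 0L, l50 = 0L))
  lens <- sort(as.integer(lens), decreasing = TRUE)
  total <- sum(lens)
  cum <- cumsum(lens)
  l50 <- which(cum >= total / 2)[1]
  out <- list(totalLength = total, nContigs = length(lens),
              largest = lens[1], n50 = lens[l50], l50 = l50)
  if (!is.null(reference)) {
    mp <- mapToReference(contigs, reference, params)
    out$coveredFraction <- mp$coveredFraction
    out$identity <- mp$identity
  }
  out
}

#' Map contigs back to a reference sequence
#'
#' Uses the assembler's own machinery (anchor chaining plus piecewise
#' banded alignment, both strands) to locate each contig on the reference
#' and measure alignment identity; intended for evaluating assemblies of
#' simulated genomes.
#'
#' @param contigs `DNAStringSet` or character vector.
#' @param reference character(1).
#' @param params parameter list from [pipelineConfig()].
#' @return list with `coveredFraction` (of the reference, by the union of
#'   contig alignments), `identity` (column-weighted mean), and `perContig`
#'   data.frame (contig, refStart, refEnd, strand, identity).
#' @export
mapToReference <- function(contigs, reference, params = pipelineConfig()) {
  seqs <- as.character(contigs)
  nms <- names(seqs) %||% paste0("contig", seq_along(seqs))
  refFwd <- as.character(reference)
  hrF <- hpc_compress_cpp(refFwd)[[1]]; hrF$rawlen <- nchar(refFwd)
  refRc <- revcompChar(refFwd)
  hrR <- hpc_compress_cpp(refRc)[[1]]; hrR$rawlen <- nchar(refRc)
  rows <- list()
  for (i in seq_along(seqs)) {
    qh <- hpc_compress_cpp(seqs[i])[[1]]; qh$rawlen <- nchar(seqs[i])
    best <- NULL; bestStrand <- "+"
    for (strand in c("+", "-")) {
      th <- if (strand == "+") hrF else hrR
      tseq <- if (strand == "+") refFwd else refRc
      anchors <- extract_anchors_cpp(qh$hseq, th$hseq, 14L)
      ch <- chainQuery(anchors, params$windowSize, params$minWindowMatch,
                       params$minChainTotal)
      if (is.null(ch)) next
      rec <- alignChainRaw(seqs[i], tseq, qh, th, ch$anchors, params)
      if (is.null(rec)) next
      if (is.null(best) || rec$score > best$score) {
        best <- rec; bestStrand <- strand
      }
    }
    if (is.null(best)) next
    ts <- best$tstart; te <- best$tend
    if (bestStrand == "-") {
      L <- nchar(refFwd)
      tmp <- L - te; te <- L - ts; ts <- tmp
    }
    rows[[length(rows) + 1L]] <-
      data.frame(contig = nms[i], refStart = ts, refEnd = te,
                 strand = bestStrand, identity = best$identity,
                 ncols = best$blockLen, stringsAsFactors = FALSE)
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), refStart = integer(0),
               refEnd = integer(0), strand = character(0),
               identity = numeric(0), ncols = integer(0))
  covered <- 0
  if (nrow(per) > 0L) {
    ir <- reduce(IRanges(start = per$refStart + 1L, end = per$refEnd))
    covered <- sum(width(ir)) / nchar(refFwd)
  }
  idn <- if (nrow(per) > 0L) sum(per$identity * per$ncols) / sum(per$ncols)
    else 0
  list(coveredFraction = covered, identity = idn, perContig = per)
}
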