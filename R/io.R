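#' Read sequences from FASTA or FASTQ
#'
#' Reads a (optionally gzip-compressed) FASTA or FASTQ file into a
#' `DNAStringSet`. Lowercase is uppercased, U is mapped to T, and any
#' other character outside {A,C,G,T,N} raises a parse error naming the
#' offending record. Read ids are implicit: position in file order minus
#' one. An empty file yields an empty set.
#'
#' @param path input file.
#' @param format "fasta", "fastq" or "auto" (default; sniffs the first
#'   record marker).
#' @return a named `DNAStringSet`.
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    first <- tryCatch(readLines(con, n = 1L), finally = close(con))
    if (length(first) == 0L) return(DNAStringSet())
    format <- if (startsWith(first, ">")) "fasta"
      else if (startsWith(first, "@")) "fastq"
      else stop("cannot detect format of ", path,
                ": first line starts with neither '>' nor '@'")
  }
  x <- readBStringSet(path, format = format)
  if (length(x) == 0L) return(DNAStringSet())
  s <- toupper(as.character(x))
  s <- chartr("U", "T", s)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    w <- which(bad)[1]
    stop("record '", names(x)[w], "' (record ", w,
         ") contains characters outside {A,C,G,T,N,U}")
  }
  if (any(!nzchar(s))) {
    w <- which(!nzchar(s))[1]
    stop("record '", names(x)[w], "' (record ", w, ") is empty")
  }
  out <- DNAStringSet(s)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write / read an overlap table
#'
#' Overlaps are serialized as PAF-compatible tab-separated columns (query
#' name, length, start, end, strand, target name, length, start, end,
#' matches, alignment block length, mapping quality) plus `sc:i:` (score),
#' `id:f:` (identity) and `cg:Z:` (edit script) tags. Coordinates are
#' 0-based half-open. The round trip is lossless given the same read
#' universe.
#'
#' @param x an [OverlapSet-class].
#' @param path output / input file.
#' @return `writeOverlaps` returns `path` invisibly; `readOverlaps`
#'   returns an [OverlapSet-class].
#' @export
writeOverlaps <- function(x, path) {
  stopifnot(is(x, "OverlapSet"))
  validObject(x)
  r <- x@records
  lines <- character(nrow(r))
  if (nrow(r) > 0L) {
    qn <- x@readNames[r$qid + 1L]; tn <- x@readNames[r$tid + 1L]
    ql <- x@readLengths[r$qid + 1L]; tl <- x@readLengths[r$tid + 1L]
    cg <- ifelse(is.na(r$cigar), "", paste0("\tcg:Z:", r$cigar))
    lines <- paste0(qn, "\t", ql, "\t", r$qstart, "\t", r$qend, "\t",
                    r$strand, "\t", tn, "\t", tl, "\t", r$tstart, "\t",
                    r$tend, "\t", r$matches, "\t", r$blockLen, "\t255",
                    "\tsc:i:", r$score,
                    "\tid:f:", formatC(r$identity, digits = 6,
                                       format = "f"), cg)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeOverlaps
#' @param readNames,readLengths the read universe (name and raw length per
#'   id, in id order). When NULL, the universe is reconstructed from the
#'   file in order of first appearance.
#' @export
readOverlaps <- function(path, readNames = NULL, readLengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new("OverlapSet", records = emptyOverlapRecords(),
               readNames = as.character(readNames %||% character(0)),
               readLengths = as.integer(readLengths %||% integer(0))))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  getTag <- function(fields, tag, default = NA_character_) {
    hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
    if (length(hit) == 0L) default else sub("^[a-z]{2}:[A-Za-z]:", "", hit[1])
  }
  df <- do.call(rbind, lapply(f, function(p) {
    if (length(p) < 12L) stop("malformed overlap line: ", paste(p, collapse = "\t"))
    data.frame(qname = p[1], qlen = as.integer(p[2]),
               qstart = as.integer(p[3]), qend = as.integer(p[4]),
               strand = p[5], tname = p[6], tlen = as.integer(p[7]),
               tstart = as.integer(p[8]), tend = as.integer(p[9]),
               matches = as.integer(p[10]), blockLen = as.integer(p[11]),
               score = as.integer(getTag(p[-(1:12)], "sc", "0")),
               identity = as.numeric(getTag(p[-(1:12)], "id", "0")),
               cigar = getTag(p[-(1:12)], "cg"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(readNames)) {
    readNames <- unique(c(df$qname, df$tname))
    readLengths <- integer(length(readNames))
    readLengths[match(df$qname, readNames)] <- df$qlen
    readLengths[match(df$tname, readNames)] <- df$tlen
  }
  qid <- match(df$qname, readNames) - 1L
  tid <- match(df$tname, readNames) - 1L
  if (anyNA(qid) || anyNA(tid))
    stop("overlap file references reads absent from the read universe")
  records <- data.frame(qid = qid, tid = tid, strand = df$strand,
                        qstart = df$qstart, qend = df$qend,
                        tstart = df$tstart, tend = df$tend,
                        matches = df$matches, blockLen = df$blockLen,
                        score = df$score, identity = df$identity,
                        cigar = df$cigar, stringsAsFactors = FALSE)
  out <- new("OverlapSet", records = records,
             readNames = as.character(readNames),
             readLengths = as.integer(readLengths))
  validObject(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a layout file
#'
#' Plain TSV: a `U` line per unitig (id, length, number of reads) followed
#' by one `R` line per tiling read (read id, name, strand, unitig offset,
#' trimmed interval start, end). Round trip is lossless.
#'
#' @param x a [Layout-class].
#' @param path output / input file.
#' @return `writeLayout` returns `path` invisibly; `readLayout` a
#'   [Layout-class].
#' @export
writeLayout <- function(x, path) {
  stopifnot(is(x, "Layout"))
  validObject(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (u in x@unitigs) {
    writeLines(paste("U", u$id, u$length, nrow(u$tiling), sep = "\t"), con)
    t <- u$tiling
    if (nrow(t))
      writeLines(paste("R", t$readId, x@readNames[t$readId + 1L],
                       t$strand, t$offset, t$start, t$end, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeLayout
#' @param readNames,readLengths the read universe; required for
#'   `readLayout` validation (lengths checked when given).
#' @export
readLayout <- function(path, readNames, readLengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  unitigsList <- list()
  cur <- NULL
  flush <- function(cur, acc) {
    if (is.null(cur)) return(acc)
    cur$tiling <- if (length(cur$rows))
      do.call(rbind, cur$rows) else emptyTiling()
    cur$rows <- NULL
    acc[[length(acc) + 1L]] <- cur
    acc
  }
  for (ln in lines) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (p[1] == "U") {
      unitigsList <- flush(cur, unitigsList)
      cur <- list(id = p[2], length = as.integer(p[3]), rows = list())
    } else if (p[1] == "R") {
      if (is.null(cur)) stop("layout file: R line before any U line")
      cur$rows[[length(cur$rows) + 1L]] <-
        data.frame(readId = as.integer(p[2]), strand = p[4],
                   offset = as.integer(p[5]), start = as.integer(p[6]),
                   end = as.integer(p[7]), stringsAsFactors = FALSE)
    } else stop("layout file: unknown line type '", p[1], "'")
  }
  unitigsList <- flush(cur, unitigsList)
  out <- new("Layout", unitigs = unitigsList,
             readNames = as.character(readNames),
             readLengths = as.integer(readLengths))
  validObject(out)
  out
}

emptyTiling <- function() {
  data.frame(readId = integer(0), strand = character(0), offset = integer(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

#' Write contigs as FASTA
#'
#' @param contigs a `DNAStringSet` (e.g. from [consensusContigs()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeContigs <- function(contigs, path) {
  writeXStringSet(as(contigs, "DNAStringSet"), path)
  invisible(path)
}
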