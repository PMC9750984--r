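#' Read motifs from a MEME-minimal text file
#'
#' Parses the minimal MEME motif format: a version line, optional
#' \code{ALPHABET}/\code{strands} lines, an optional
#' \code{Background letter frequencies} block, then one or more
#' \code{MOTIF <name>} blocks each followed by a
#' \code{letter-probability matrix:} header and \code{w} rows of four
#' probabilities (A C G T order).
#'
#' @param path motif text file.
#' @param background optional named A,C,G,T frequencies overriding the
#'   file's background block (uniform when neither is present).
#' @return named list of \linkS4class{MotifMatrix}.
#' @export
readMeme <- function(path, background = NULL) {
  lines <- trimws(readLines(path))
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  i <- grep("^Background letter frequencies", lines)
  if (length(i)) {
    toks <- strsplit(paste(lines[i[1] + 1], collapse = " "), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    lab <- toupper(toks[is.na(vals)])
    num <- vals[!is.na(vals)]
    if (length(lab) == 4 && length(num) == 4) {
      names(num) <- lab
      bg <- num[c("A", "C", "G", "T")]
    }
  }
  if (!is.null(background)) bg <- background[c("A", "C", "G", "T")]
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path, call. = FALSE)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(lines[s], "\\s+")[[1]][2]
    h <- s + grep("^letter-probability matrix", lines[seq(s + 1,
                  length(lines))])[1]
    if (is.na(h)) stop("motif ", name, ": missing matrix header",
                       call. = FALSE)
    w <- suppressWarnings(as.integer(
      sub(".*w=\\s*(\\d+).*", "\\1", lines[h])))
    rows <- list()
    j <- h + 1
    while (j <= length(lines) && length(rows) < ifelse(is.na(w), 1e6, w)) {
      vals <- suppressWarnings(as.numeric(strsplit(lines[j], "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals)) break
      rows[[length(rows) + 1]] <- vals
      j <- j + 1
    }
    if (!is.na(w) && length(rows) != w)
      stop("motif ", name, ": expected ", w, " matrix rows, found ",
           length(rows), call. = FALSE)
    m <- t(do.call(rbind, rows))
    rownames(m) <- c("A", "C", "G", "T")
    motifs[[name]] <- MotifMatrix(name, m, background = bg)
  }
  motifs
}

#' Write motifs in MEME-minimal format
#'
#' @param motifs a \linkS4class{MotifMatrix} or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMeme <- function(motifs, path) {
  if (is(motifs, "MotifMatrix")) motifs <- list(motifs)
  bg <- motifs[[1]]@background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "", "Background letter frequencies",
           paste(sprintf("%s %.6g", names(bg), bg), collapse = " "), "")
  for (m in motifs) {
    p <- motifProbs(m)
    out <- c(out, paste("MOTIF", motifName(m)),
             sprintf("letter-probability matrix: alength= 4 w= %d", ncol(p)),
             apply(p, 2, function(col)
               paste(sprintf("%.6f", col), collapse = " ")), "")
  }
  writeLines(out, path)
  invisible(path)
}
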