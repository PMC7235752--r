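# Readers and writers for the external formats: FASTA, relaxed PHYLIP,
# NEXUS (DATA + SETS/CHARSET), newick trees and PAML-style rate-matrix files.
# FASTA parsing is delegated to seqinr; newick handling to ape. The NEXUS,
# PHYLIP and PAML dialects are implemented here (no installed package parses
# CHARSET blocks, generic-alphabet PHYLIP, or PAML lower-triangle files).

#' Read a multiple sequence alignment
#'
#' @param path file path.
#' @param format `"FASTA"`, `"PHYLIP"` or `"NEXUS"`; inferred from the file
#'   extension when omitted.
#' @param alphabet declared alphabet of the data (`"AA20"`, `"STATE6"`,
#'   `"BINARY"`). For NEXUS input the FORMAT line, when present, overrides
#'   this.
#' @return an [alignment()] with `gene_map` populated from NEXUS CHARSET
#'   blocks when present.
#' @export
read_alignment <- function(path, format = NULL, alphabet = "AA20") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      fa = , fas = , fasta = "FASTA",
      phy = , phylip = "PHYLIP",
      nex = , nexus = , nxs = "NEXUS",
      stop("cannot infer format from extension '", ext, "'"))
  }
  switch(toupper(format),
    FASTA  = .read_fasta(path, alphabet),
    PHYLIP = .read_phylip(path, alphabet),
    NEXUS  = .read_nexus(path, alphabet),
    stop("unknown format: ", format))
}

.read_fasta <- function(path, alphabet) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  if (!length(seqs)) stop("alignment-shape error: no sequences in ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1)
    stop("alignment-shape error: ragged rows (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  m <- do.call(rbind, lapply(seqs, toupper))
  alignment(m, alphabet = alphabet, taxon_names = names(seqs))
}

.read_phylip <- function(path, alphabet) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hd) < 2 || anyNA(hd))
    stop("alignment-shape error: bad PHYLIP header")
  ntax <- hd[1]; nchar_ <- hd[2]
  nm <- character(0); seqs <- list()
  for (ln in lines[-1]) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(nm) < ntax &&
        (length(nm) == 0 || nchar(paste(seqs[[length(nm)]], collapse = "")) >= nchar_)) {
      nm <- c(nm, toks[1])
      seqs[[length(nm)]] <- toks[-1]
    } else {
      seqs[[length(nm)]] <- c(seqs[[length(nm)]], toks)
    }
  }
  if (length(nm) != ntax)
    stop("alignment-shape error: expected ", ntax, " taxa, found ", length(nm))
  rows <- vapply(seqs, function(s) paste(s, collapse = ""), "")
  if (any(nchar(rows) != nchar_))
    stop("alignment-shape error: ragged rows in PHYLIP body")
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  alignment(m, alphabet = alphabet, taxon_names = nm)
}

# NEXUS: DATA (or CHARACTERS) block with optional interleaving, plus a
# SETS block with CHARSET lines (1-based inclusive ranges).
.read_nexus <- function(path, alphabet) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("\\[[^]]*\\]", "", txt)          # strip single-line comments
  joined <- paste(txt, collapse = "\n")
  dt <- regmatches(joined, regexpr("(?i)datatype\\s*=\\s*[A-Za-z]+", joined))
  if (length(dt)) {
    dtv <- tolower(sub("(?i)datatype\\s*=\\s*", "", dt, perl = TRUE))
    if (dtv == "protein") alphabet <- "AA20"
  }
  sym <- regmatches(joined, regexpr('(?i)symbols\\s*=\\s*"[^"]*"', joined))
  if (length(sym)) {
    symset <- strsplit(gsub('.*"([^"]*)".*', "\\1", sym), "")[[1]]
    symset <- setdiff(symset, " ")
    if (setequal(symset, BINARY_ORDER)) alphabet <- "BINARY"
    else if (setequal(symset, STATE6_ORDER)) alphabet <- "STATE6"
  }
  up <- toupper(txt)
  mstart <- grep("^\\s*MATRIX\\s*$", up)
  if (!length(mstart)) stop("parse error: no MATRIX keyword in NEXUS file")
  mend <- grep(";", txt[(mstart[1] + 1):length(txt)], fixed = TRUE)[1] + mstart[1]
  body <- txt[(mstart[1] + 1):(mend - 1)]
  body <- body[nzchar(trimws(body))]
  nm <- character(0); seqs <- list()
  for (ln in body) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    name <- gsub("^'|'$", "", toks[1])
    chunk <- paste(toks[-1], collapse = "")
    i <- match(name, nm)
    if (is.na(i)) { nm <- c(nm, name); seqs[[length(nm)]] <- chunk }
    else seqs[[i]] <- paste0(seqs[[i]], chunk)
  }
  rows <- unlist(seqs)
  if (length(unique(nchar(rows))) != 1)
    stop("alignment-shape error: ragged rows in NEXUS matrix")
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  gm <- .parse_charsets(txt, ncol(m))
  alignment(m, alphabet = alphabet, taxon_names = nm, gene_map = gm)
}

.parse_charsets <- function(txt, ncols) {
  cs <- grep("(?i)^\\s*charset\\s", txt, perl = TRUE, value = TRUE)
  if (!length(cs)) return(NULL)
  out <- lapply(cs, function(ln) {
    ln <- sub(";.*$", "", ln)
    m <- regmatches(ln, regexec("(?i)charset\\s+(\\S+)\\s*=\\s*(.+)", ln,
                                perl = TRUE))[[1]]
    if (length(m) < 3) stop("parse error: bad CHARSET line: ", ln)
    name <- m[2]
    parts <- strsplit(trimws(m[3]), "\\s+")[[1]]
    idx <- unlist(lapply(parts, function(p) {
      if (grepl("-", p)) {
        ab <- as.integer(strsplit(p, "-")[[1]])
        seq(ab[1], ab[2])
      } else as.integer(p)
    }))
    if (any(idx < 1 | idx > ncols))
      stop("bounds error: CHARSET '", name, "' outside 1..", ncols)
    data.frame(gene = name, start = min(idx), end = max(idx))
  })
  do.call(rbind, out)
}

#' Write an alignment (FASTA, PHYLIP or NEXUS)
#'
#' @param aln an [alignment()].
#' @param path output file path.
#' @param format `"FASTA"`, `"PHYLIP"` or `"NEXUS"`.
#' @param charsets optional charset table (data.frame `gene`,`start`,`end`,
#'   1-based closed) written to a NEXUS SETS block; defaults to the
#'   alignment's own `gene_map`.
#' @export
write_alignment <- function(aln, path, format = "NEXUS", charsets = NULL) {
  switch(toupper(format),
    FASTA = {
      rows <- apply(aln$matrix, 1, paste, collapse = "")
      writeLines(paste0(">", names(rows), "\n", rows), path)
    },
    PHYLIP = {
      rows <- apply(aln$matrix, 1, paste, collapse = "")
      writeLines(c(paste(n_taxa(aln), n_cols(aln)),
                   paste(format(names(rows), width = 12), rows)), path)
    },
    NEXUS = write_nexus(aln, charsets = charsets, path = path),
    stop("unknown format: ", format))
  invisible(path)
}

#' Write a NEXUS file with DATA and SETS blocks
#'
#' CHARSET ranges are emitted 1-based inclusive with contiguous runs
#' collapsed to `start-end`. An empty charset table yields a valid NEXUS
#' file without a SETS block.
#'
#' @inheritParams write_alignment
#' @export
write_nexus <- function(aln, charsets = NULL, path) {
  if (is.null(charsets)) charsets <- aln$gene_map
  if (!is.null(charsets) && nrow(charsets)) {
    if (any(charsets$start < 1 | charsets$end > n_cols(aln) |
            charsets$start > charsets$end))
      stop("bounds error: charset outside alignment columns")
  }
  fmt <- switch(aln$alphabet,
    AA20   = sprintf("format datatype=protein gap=%s missing=%s;",
                     aln$gap, aln$missing),
    STATE6 = sprintf('format datatype=standard symbols="012345" gap=%s missing=%s;',
                     aln$gap, aln$missing),
    BINARY = sprintf('format datatype=standard symbols="01" gap=%s missing=%s;',
                     aln$gap, aln$missing))
  rows <- apply(aln$matrix, 1, paste, collapse = "")
  width <- max(nchar(names(rows))) + 2
  out <- c("#NEXUS", "", "begin data;",
           sprintf("dimensions ntax=%d nchar=%d;", n_taxa(aln), n_cols(aln)),
           fmt, "matrix",
           paste0(format(names(rows), width = width), rows),
           ";", "end;")
  if (!is.null(charsets) && nrow(charsets)) {
    lines <- sprintf("charset %s = %d-%d;",
                     charsets$gene, charsets$start, charsets$end)
    out <- c(out, "", "begin sets;", lines, "end;")
  }
  writeLines(out, path)
  invisible(path)
}

#' Parse and serialize newick trees
#'
#' Thin wrappers over ape. Branch lengths absent from the newick string
#' default to 0.
#'
#' @param text a newick string.
#' @return [parse_tree()]: an ape `phylo`; [serialize_tree()]: a newick
#'   string.
#' @export
parse_tree <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("parse error: malformed newick: ", text)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("domain error: branch lengths must be finite and non-negative")
  tr
}

#' @rdname parse_tree
#' @param tree an ape `phylo` object.
#' @export
serialize_tree <- function(tree) ape::write.tree(tree)

#' Read a PAML-style amino-acid rate-matrix file
#'
#' The file holds the 19-row lower triangle of the 190 exchangeabilities
#' (canonical order ARNDCQEGHILKMFPSTWYV) followed by the 20 equilibrium
#' frequencies. Comments after the frequencies are ignored.
#'
#' @param path file path.
#' @return list with `rates` (190 values, column-wise pair order) and
#'   `frequencies` (20 values summing to 1).
#' @export
read_rate_matrix <- function(path) {
  toks <- scan(path, what = "", quiet = TRUE, comment.char = "#")
  vals <- suppressWarnings(as.numeric(toks))
  vals <- vals[!is.na(vals)]
  if (length(vals) < 210)
    stop("shape error: expected 190 exchangeabilities + 20 frequencies, found ",
         length(vals), " numbers")
  tri <- vals[1:190]
  freqs <- vals[191:210]
  if (any(tri < 0) || any(freqs < 0))
    stop("domain error: negative value in rate-matrix file")
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("validation error: frequencies sum to ", sum(freqs))
  freqs <- freqs / sum(freqs)
  # PAML triangles are written row-wise ((2,1);(3,1)(3,2);...); convert to
  # the package's column-wise pair order.
  m <- matrix(0, 20, 20)
  k <- 1
  for (i in 2:20) for (j in 1:(i - 1)) { m[i, j] <- tri[k]; k <- k + 1 }
  list(rates = m[lower.tri(m)], frequencies = freqs)
}

#' @rdname read_rate_matrix
#' @param rates 190 exchangeabilities (column-wise pair order).
#' @param frequencies 20 equilibrium frequencies.
#' @export
write_rate_matrix <- function(rates, frequencies, path) {
  stopifnot(length(rates) == 190, length(frequencies) == 20)
  m <- exch_vec_to_mat(rates, 20)
  rows <- vapply(2:20, function(i)
    paste(format(m[i, 1:(i - 1)], digits = 10, trim = TRUE), collapse = " "), "")
  writeLines(c(rows, "",
               paste(format(frequencies, digits = 10, trim = TRUE),
                     collapse = " ")), path)
  invisible(path)
}
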