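#' Build a gene set
#'
#' A gene set is the unit all downstream analyses consume: an ordered,
#' uniquely named collection of coding sequences from one species, tied to
#' one genetic code.
#'
#' @param sequences Named character vector of DNA sequences (names are gene
#'   ids), or a `Biostrings::DNAStringSet`.
#' @param species_id Species label.
#' @param code A [genetic_code()]; defaults to the vertebrate mitochondrial
#'   code (table 2).
#' @return Object of class `gene_set` with elements `species_id`, `genes`
#'   (named character vector, uppercase DNA) and `code`.
#' @export
gene_set <- function(sequences, species_id = "species", code = genetic_code(2)) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) &&
      (is.null(names(sequences)) || anyNA(names(sequences)) ||
       any(names(sequences) == ""))) {
    stop("all sequences must be named by gene id")
  }
  if (length(sequences) == 0) sequences <- setNames(character(0), character(0))
  if (anyDuplicated(names(sequences))) {
    stop("duplicate gene ids: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  }
  genes <- toupper(chartr("Uu", "Tt", sequences))
  structure(list(species_id = species_id, genes = genes, code = code),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set: ", x$species_id, " — ", length(x$genes), " gene(s), code table ",
      x$code$table_id, "\n", sep = "")
  cat("  ", paste(sprintf("%s (%d bp)", names(x$genes), nchar(x$genes)),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Load coding sequences from FASTA or GenBank
#'
#' FASTA records become genes named by the first word of their headers.
#' GenBank mode extracts CDS features from a flat file, honouring
#' `complement()`/`join()` locations, and names each gene by its `/gene=`
#' (falling back to `/product=`) qualifier. Sequences are uppercased and
#' U is normalised to T.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"genbank"`; default guesses from the
#'   extension (`.gb`, `.gbk`, `.gbff` = GenBank).
#' @param species_id Species label; default is the file base name (FASTA) or
#'   the record accession (GenBank).
#' @param code A [genetic_code()].
#' @return A [gene_set()]. A GenBank record without CDS features yields an
#'   empty set with a warning.
#' @export
load_sequences <- function(path, format = c("auto", "fasta", "genbank"),
                           species_id = NULL, code = genetic_code(2)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "fasta") {
    # read as raw strings so RNA spelling (U) can be normalised, not dropped
    seqs <- tryCatch(Biostrings::readBStringSet(path),
                     error = function(e) stop("cannot parse FASTA '", path,
                                              "': ", conditionMessage(e)))
    nm <- sub("\\s.*$", "", names(seqs))
    if (is.null(species_id)) {
      species_id <- sub("\\.[^.]*$", "", basename(path))
    }
    gene_set(setNames(as.character(seqs), nm), species_id, code)
  } else {
    rec <- parse_genbank_cds(path)
    if (is.null(species_id)) species_id <- rec$accession
    if (length(rec$cds) == 0) {
      warning("no CDS features in GenBank file '", path, "'")
    }
    gene_set(rec$cds, species_id, code)
  }
}

# Minimal GenBank flat-file reader: returns accession and the extracted CDS
# sequences of the first record. Handles join(), complement(), and partial
# markers (<, >) in feature locations.
parse_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file: ", path)
  }
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[1])

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank file has no ORIGIN section: ", path)
  end <- grep("^//", lines)
  end <- if (length(end)) end[1] else length(lines) + 1
  seq_lines <- lines[(ori[1] + 1):(end - 1)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat <- grep("^FEATURES", lines)
  if (!length(feat)) stop("GenBank file has no FEATURES section: ", path)
  flines <- lines[(feat[1] + 1):(ori[1] - 1)]
  # feature starts: 5 leading spaces then a key
  starts <- grep("^ {5}\\S", flines)
  cds <- character(0)
  for (i in seq_along(starts)) {
    key <- sub("^ {5}(\\S+).*$", "\\1", flines[starts[i]])
    if (key != "CDS") next
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(flines)
    block <- flines[starts[i]:to]
    # location may wrap before the first qualifier line
    qual_at <- grep("^\\s+/", block)
    loc_end <- if (length(qual_at)) qual_at[1] - 1 else length(block)
    loc <- paste(trimws(c(sub("^ {5}CDS\\s+", "", block[1]),
                          block[seq_len(loc_end)[-1]])), collapse = "")
    qual <- paste(block[-seq_len(loc_end)], collapse = "\n")
    name <- genbank_qualifier(qual, "gene")
    if (is.na(name)) name <- genbank_qualifier(qual, "product")
    if (is.na(name)) name <- paste0("CDS_", length(cds) + 1)
    seqv <- extract_location(genome, loc)
    nm <- make.unique(c(names(cds), name))[length(cds) + 1]
    cds[nm] <- seqv
  }
  list(accession = accession, cds = cds)
}

genbank_qualifier <- function(text, what) {
  m <- regmatches(text, regexpr(sprintf('/%s="[^"]*"', what), text))
  if (!length(m)) {
    m <- regmatches(text, regexpr(sprintf("/%s=[^\\s/]+", what), text))
    if (!length(m)) return(NA_character_)
    return(sub(sprintf("/%s=", what), "", m))
  }
  sub(sprintf('/%s="([^"]*)"', what), "\\1", m)
}

extract_location <- function(genome, loc) {
  loc <- gsub("[<>\\s]", "", loc)
  comp <- grepl("^complement\\(", loc)
  if (comp) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  piece <- vapply(parts, function(p) {
    p_comp <- grepl("^complement\\(", p)
    if (p_comp) p <- sub("^complement\\((.*)\\)$", "\\1", p)
    rng <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(rng) == 1) rng <- c(rng, rng)
    s <- substr(genome, rng[1], rng[2])
    if (p_comp) s <- revcomp(s)
    s
  }, character(1))
  out <- paste(piece, collapse = "")
  if (comp) out <- revcomp(out)
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write a gene set to FASTA
#'
#' @param genes A [gene_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genes, path) {
  stopifnot(inherits(genes, "gene_set"))
  x <- Biostrings::DNAStringSet(genes$genes)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# trim a terminal stop codon (complete, and any 1-2 bp partial codon first)
trim_terminal_stop <- function(seq, code) {
  extra <- nchar(seq) %% 3
  if (extra > 0) seq <- substr(seq, 1, nchar(seq) - extra)
  n <- nchar(seq)
  if (n >= 3) {
    last <- substr(seq, n - 2, n)
    if (last %in% code$stop_codons) seq <- substr(seq, 1, n - 3)
  }
  seq
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return(character(0))
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# positions (codon index) of internal stop codons after terminal-stop trimming
internal_stops <- function(seq, code) {
  cods <- split_codons(trim_terminal_stop(seq, code))
  which(cods %in% code$stop_codons)
}

#' Filter coding sequences by quality rules
#'
#' Retains genes that (i) are at least `min_length_bp` long, (ii) start with
#' `require_start`, (iii) contain no internal stop codons under the active
#' code, and (iv) are not an exact duplicate of an already retained gene.
#' Partial trailing codons and a complete terminal stop are trimmed before
#' the stop-codon check (mitochondrial CDS often end on incomplete stops
#' completed by polyadenylation).
#'
#' @param genes A [gene_set()].
#' @param min_length_bp Minimum raw length in bp (default 300).
#' @param require_start Required initiator codon (default `"ATG"`); `NULL`
#'   disables the check.
#' @return The filtered [gene_set()], with a `filter_report` attribute: a
#'   data.frame (gene_id, length_bp, start_codon, kept, reason).
#' @export
filter_cds <- function(genes, min_length_bp = 300, require_start = "ATG") {
  stopifnot(inherits(genes, "gene_set"))
  if (length(genes$genes) == 0) stop("gene set is empty")
  code <- genes$code
  ids <- names(genes$genes)
  report <- data.frame(
    gene_id = ids,
    length_bp = unname(nchar(genes$genes)),
    start_codon = unname(substr(genes$genes, 1, 3)),
    kept = TRUE, reason = "", stringsAsFactors = FALSE
  )
  kept_seqs <- character(0)
  for (i in seq_along(ids)) {
    s <- genes$genes[[i]]
    reason <- NULL
    if (nchar(s) < min_length_bp) {
      reason <- "length"
    } else if (!is.null(require_start) && substr(s, 1, 3) != require_start) {
      reason <- "start codon"
    } else if (length(internal_stops(s, code)) > 0) {
      reason <- "internal stop"
    } else if (s %in% kept_seqs) {
      reason <- "duplicate sequence"
    }
    if (is.null(reason)) {
      kept_seqs <- c(kept_seqs, s)
    } else {
      report$kept[i] <- FALSE
      report$reason[i] <- reason
    }
  }
  if (!any(report$kept)) stop("empty after filtering: no gene passed")
  out <- gene_set(genes$genes[report$kept], genes$species_id, code)
  attr(out, "filter_report") <- report
  out
}

#' Write a CDS filter report as TSV
#'
#' @param genes A filtered [gene_set()] carrying a `filter_report` attribute.
#' @param path Output TSV path.
#' @export
write_filter_report <- function(genes, path) {
  rep <- attr(genes, "filter_report")
  if (is.null(rep)) stop("gene set has no filter report (run filter_cds first)")
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Translates codon-by-codon under the given code. A trailing complete stop
#' codon is dropped; codons containing N (or other ambiguity letters)
#' translate to `X`.
#'
#' @param seq DNA string, length a multiple of 3 (a trailing 1-2 bp partial
#'   codon is trimmed).
#' @param code A [genetic_code()].
#' @return Single amino-acid string, one letter per codon.
#' @export
translate_cds <- function(seq, code = genetic_code(2)) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  seq <- trim_terminal_stop(seq, code)
  cods <- split_codons(seq)
  bad <- which(cods %in% code$stop_codons)
  if (length(bad)) {
    stop("internal stop codon at codon position ", bad[1])
  }
  aa <- code$codon_to_aa[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
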