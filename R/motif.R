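## 9-mer phosphosite motifs: extraction from protein sequence and
## decomposition into positional amino-acid triples.

#' Amino-acid alphabet used for motif nodes
#'
#' The 20 standard residues plus the terminal-padding symbol `"_"` and the
#' catch-all `"X"` for nonstandard residues.
#'
#' @return Character vector of allowed motif characters.
#' @export
motif_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "_")
}

## nonstandard residues collapsed onto X; keeps the alphabet closed without
## silently dropping characters
.nonstandard_map <- c(U = "X", B = "X", Z = "X", O = "X", J = "X", "*" = "X")

#' Normalize a motif string to the closed alphabet
#'
#' Upper-cases and maps nonstandard residues (U, B, Z, O, J) to `"X"`.
#' Characters outside the amino-acid alphabet that are not recognized
#' nonstandard codes raise an error: they are never silently dropped.
#'
#' @param x character vector of motif or sequence strings.
#' @return Normalized character vector.
#' @export
normalize_motif <- function(x) {
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(cc) {
    hit <- cc %in% names(.nonstandard_map)
    cc[hit] <- .nonstandard_map[cc[hit]]
    bad <- !(cc %in% motif_alphabet())
    if (any(bad)) {
      stop("invalid motif character(s): ",
           paste(unique(cc[bad]), collapse = ", "), call. = FALSE)
    }
    paste(cc, collapse = "")
  }, character(1))
}

#' Extract the 9-mer motif around a phosphosite
#'
#' Takes the window of four residues upstream and four downstream of the
#' phosphoacceptor (site position, 1-based). Positions falling outside the
#' protein are filled with the padding symbol `"_"`, so the result always
#' has length 9 with the phosphoacceptor at position 5.
#'
#' @param sequence protein sequence (single string).
#' @param site 1-based residue position of the phosphosite; the residue at
#'   this position must be S, T or Y.
#' @param pad padding symbol for positions beyond the termini.
#' @return A 9-character motif string.
#' @examples
#' extract_motif("STY", 1)  # "____STY__"
#' @export
extract_motif <- function(sequence, site, pad = "_") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_motif(sequence)
  n <- nchar(sequence)
  if (!is.numeric(site) || length(site) != 1L || site < 1L || site > n) {
    stop("site ", site, " out of range for sequence of length ", n,
         call. = FALSE)
  }
  site <- as.integer(site)
  center <- substr(sequence, site, site)
  if (!center %in% c("S", "T", "Y")) {
    stop("residue at site ", site, " is '", center,
         "', not a phosphoacceptor (S/T/Y)", call. = FALSE)
  }
  pos <- (site - 4L):(site + 4L)
  chars <- ifelse(pos < 1L | pos > n, pad,
                  substring(sequence, pos, pos))
  paste(chars, collapse = "")
}

#' Encode a 9-mer motif as nine positional residue triples
#'
#' Each motif node connects to nine amino-acid nodes: triple i has the motif
#' string as head, relation `residue_i`, and tail `aa_<char>` where `<char>`
#' is the residue at position i (the padding symbol maps to node `aa__`).
#'
#' @param motif 9-character motif string (padding allowed).
#' @param phosphosite if `TRUE`, require the center (position 5) to be a
#'   phosphoacceptor residue (S/T/Y).
#' @return A `data.table` of 9 rows with columns `head`, `relation`, `tail`.
#' @examples
#' encode_motif("SSPSTPVGS")
#' @export
encode_motif <- function(motif, phosphosite = TRUE) {
  stopifnot(is.character(motif), length(motif) == 1L)
  motif <- normalize_motif(motif)
  if (nchar(motif) != 9L) {
    stop("motif must have length 9, got ", nchar(motif), " ('", motif, "')",
         call. = FALSE)
  }
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (phosphosite && !chars[5L] %in% c("S", "T", "Y")) {
    stop("motif center '", chars[5L], "' is not a phosphoacceptor (S/T/Y)",
         call. = FALSE)
  }
  data.table(
    head = motif,
    relation = residue_relations(),
    tail = paste0("aa_", chars)
  )
}

#' Encode many motifs at once
#'
#' Vectorized form of [encode_motif()]: one call for a character vector of
#' unique 9-mers, returning the concatenated triple table.
#'
#' @param motifs character vector of 9-character motif strings.
#' @param phosphosite require S/T/Y centers (see [encode_motif()]).
#' @return `data.table` with `9 * length(motifs)` rows.
#' @export
encode_motifs <- function(motifs, phosphosite = TRUE) {
  if (length(motifs) == 0L) {
    return(data.table(head = character(), relation = character(),
                      tail = character()))
  }
  motifs <- normalize_motif(motifs)
  if (any(nchar(motifs) != 9L)) {
    bad <- motifs[nchar(motifs) != 9L]
    stop("motifs must have length 9; offending: ",
         paste(head(bad, 3L), collapse = ", "), call. = FALSE)
  }
  centers <- substr(motifs, 5L, 5L)
  if (phosphosite && any(!centers %in% c("S", "T", "Y"))) {
    stop("non-phosphoacceptor motif center(s): ",
         paste(head(unique(centers[!centers %in% c("S", "T", "Y")]), 3L),
               collapse = ", "), call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(motifs, "", fixed = TRUE)),
                  nrow = length(motifs), byrow = TRUE)
  data.table(
    head = rep(motifs, each = 9L),
    relation = rep(residue_relations(), times = length(motifs)),
    tail = paste0("aa_", as.vector(t(chars)))
  )
}
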