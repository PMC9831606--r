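#' Registry of extended (non-canonical) residue codes
#'
#' Knottin optimization campaigns routinely use non-canonical amino acids to
#' tune stability or membrane interactions: norarginine, norleucine (an
#' oxidation-resistant methionine replacement), 2,4-dimethyl-phenylalanine and
#' tert-butyl-cysteine. Each extended code has a unique single display
#' character for compact alignments (norarginine displays as "X") and a
#' canonical parent residue it is most closely derived from. The registry is
#' an ordinary data.frame, so additional codes can be appended by the user.
#'
#' Display characters are deliberately drawn from letters with no canonical
#' one-letter meaning (X, Z, B, J) so they cannot be misread as canonical
#' residues within a sequence.
#'
#' @return A data.frame with columns `code`, `display`, `parent`,
#'   `description`.
#' @export
extended_residues <- function() {
  data.frame(
    code        = c("norArg", "norLeu", "dmF", "tbC"),
    display     = c("X", "Z", "B", "J"),
    parent      = c("R", "L", "F", "C"),
    description = c("norarginine", "norleucine",
                    "2,4-dimethyl-phenylalanine", "tert-butyl-cysteine"),
    stringsAsFactors = FALSE
  )
}

.CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.check_registry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("code", "display", "parent") %in% names(registry)))
  if (anyDuplicated(registry$code) || anyDuplicated(registry$display))
    stop("extended-residue registry has duplicated codes or display characters")
  if (any(registry$display %in% .CANONICAL_AA))
    stop("extended-residue display characters must not collide with canonical codes")
  invisible(registry)
}

# Is each element of `res` a valid residue code under the registry?
.valid_residue <- function(res, registry = extended_residues()) {
  res %in% c(.CANONICAL_AA, registry$code)
}

# Map residue codes to their single display character.
residue_display <- function(res, registry = extended_residues()) {
  .check_registry(registry)
  m <- match(res, registry$code)
  out <- ifelse(is.na(m), res, registry$display[m])
  bad <- !(out %in% c(.CANONICAL_AA, registry$display))
  if (any(bad)) stop("unknown residue code(s): ", paste(unique(res[bad]), collapse = ", "))
  out
}

# Decode display characters (single letters) into residue codes.
decode_display <- function(chars, registry = extended_residues()) {
  .check_registry(registry)
  m <- match(chars, registry$display)
  out <- ifelse(is.na(m), chars, registry$code[m])
  bad <- !.valid_residue(out, registry)
  if (any(bad))
    stop("unknown display character(s): ", paste(unique(chars[bad]), collapse = ", "))
  out
}

#' Construct a peptide variant
#'
#' A named peptide in a knottin optimization series: an ordered vector of
#' residue codes (canonical one-letter codes or extended codes from the
#' registry), a C-terminal amidation flag (metadata only), and an optional
#' parent variant name.
#'
#' @param name Variant identifier, e.g. `"PTx2-3127"`.
#' @param residues Either a character vector of residue codes (one per
#'   position) or a single display string that is split into characters and
#'   decoded through the registry.
#' @param c_terminal_amidated Logical; whether the C-terminus is amidated.
#' @param parent Optional identifier of the parent variant.
#' @param registry Extended-residue registry (see [extended_residues()]).
#' @return An object of class `peptide_variant`.
#' @export
peptide_variant <- function(name, residues, c_terminal_amidated = TRUE,
                            parent = NULL, registry = extended_residues()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- decode_display(strsplit(residues, "")[[1]], registry)
  residues <- as.character(residues)
  bad <- which(!.valid_residue(residues, registry))
  if (length(bad))
    stop(sprintf("invalid residue code '%s' at position %d of '%s'",
                 residues[bad[1]], bad[1], name))
  structure(
    list(name = name, residues = residues,
         c_terminal_amidated = isTRUE(c_terminal_amidated),
         parent = parent, registry = registry),
    class = "peptide_variant"
  )
}

#' @export
length.peptide_variant <- function(x) length(x$residues)

#' Compact single-character display string of a variant
#'
#' Extended residues are rendered with their registry display character
#' (norarginine as "X", etc.).
#'
#' @param v A `peptide_variant`.
#' @return A single string of length-of-peptide characters.
#' @export
display_string <- function(v) {
  stopifnot(inherits(v, "peptide_variant"))
  paste(residue_display(v$residues, v$registry), collapse = "")
}

#' @export
print.peptide_variant <- function(x, ...) {
  cat(sprintf("<peptide_variant> %s (%d aa%s%s)\n  %s\n", x$name, length(x),
              if (x$c_terminal_amidated) ", C-term amide" else "",
              if (!is.null(x$parent)) paste0(", parent ", x$parent) else "",
              display_string(x)))
  invisible(x)
}

#' Parse a variant alignment table
#'
#' Reads a delimited table whose header is a name column followed by residue
#' numbers 1..L and whose rows are variants with one display character per
#' cell (the layout used for round-by-round optimization summaries). Display
#' characters are decoded through the extended-residue registry, so an "X"
#' cell becomes norarginine.
#'
#' @param path Path to a TSV/CSV file, or a character vector of lines.
#' @param sep Field separator (default tab).
#' @param registry Extended-residue registry.
#' @return A named list of [peptide_variant()] objects, in row order.
#' @export
parse_variant_table <- function(path, sep = "\t", registry = extended_residues()) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty variant table")
  cells <- strsplit(lines, sep, fixed = TRUE)
  hdr <- trimws(cells[[1]])
  pos <- suppressWarnings(as.integer(hdr[-1]))
  if (anyNA(pos) || !identical(pos, seq_along(pos)))
    stop("variant table header must be a name column followed by residue numbers 1..L")
  L <- length(pos)
  if (length(cells) == 1L) return(structure(list(), names = character(0)))
  out <- list()
  for (r in 2:length(cells)) {
    row <- trimws(cells[[r]])
    if (length(row) != L + 1L)
      stop(sprintf("ragged row %d ('%s'): expected %d cells, got %d",
                   r - 1L, row[1], L + 1L, length(row)))
    res <- tryCatch(decode_display(row[-1], registry), error = function(e)
      stop(sprintf("row '%s': %s", row[1], conditionMessage(e)), call. = FALSE))
    out[[row[1]]] <- peptide_variant(row[1], res, registry = registry)
  }
  out
}

#' Construct a mutation set
#'
#' @param position Integer vector of 1-based positions.
#' @param from,to Character vectors of residue codes.
#' @return An object of class `mutation_set`: a data.frame with columns
#'   `position`, `from`, `to`, sorted by position.
#' @export
mutation_set <- function(position = integer(0), from = character(0),
                         to = character(0)) {
  stopifnot(length(position) == length(from), length(from) == length(to))
  if (anyDuplicated(position)) stop("mutation positions must be unique")
  if (any(from == to)) stop("mutations must change the residue (from != to)")
  o <- order(position)
  structure(
    data.frame(position = as.integer(position[o]), from = from[o], to = to[o],
               stringsAsFactors = FALSE),
    class = c("mutation_set", "data.frame")
  )
}

#' Render a mutation set in standard notation
#'
#' Produces tokens like `"Y1H"` or `"R22norArg"` (extended residues keep
#' their full code so the notation stays unambiguous).
#'
#' @param m A `mutation_set`.
#' @param collapse Separator used to join tokens (default `","`).
#' @return A single string, or `character(0)` for an empty set.
#' @export
format_mutations <- function(m, collapse = ",") {
  stopifnot(inherits(m, "mutation_set"))
  if (nrow(m) == 0L) return("")
  paste(paste0(m$from, m$position, m$to), collapse = collapse)
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(sprintf("<mutation_set> %d mutation(s): %s\n", nrow(x),
              if (nrow(x)) format_mutations(x) else "(none)"))
  invisible(x)
}

#' Parse mutation tokens
#'
#' Inverse of [format_mutations()]: parses `"Y1H,W7Q,R22norArg"` into a
#' mutation set.
#'
#' @param text A single string of comma-separated tokens (or a character
#'   vector of tokens).
#' @param registry Extended-residue registry used to validate codes.
#' @return A `mutation_set`.
#' @export
parse_mutations <- function(text, registry = extended_residues()) {
  toks <- unlist(strsplit(text, ",", fixed = TRUE))
  toks <- trimws(toks[nzchar(trimws(toks))])
  if (length(toks) == 0L) return(mutation_set())
  m <- regmatches(toks, regexec("^([A-Za-z]+?)([0-9]+)([A-Za-z]+)$", toks))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("cannot parse mutation token(s): ",
                     paste(toks[bad], collapse = ", "))
  from <- vapply(m, `[`, "", 2L)
  pos  <- as.integer(vapply(m, `[`, "", 3L))
  to   <- vapply(m, `[`, "", 4L)
  ok <- .valid_residue(from, registry) & .valid_residue(to, registry)
  if (any(!ok)) stop("unknown residue code in token(s): ",
                     paste(toks[!ok], collapse = ", "))
  mutation_set(pos, from, to)
}

#' Differences between two peptide variants
#'
#' Position-wise comparison of two equal-length variants, reported as
#' mutations a -> b.
#'
#' @param a,b `peptide_variant` objects of equal length.
#' @return A `mutation_set`.
#' @export
diff_variants <- function(a, b) {
  stopifnot(inherits(a, "peptide_variant"), inherits(b, "peptide_variant"))
  if (length(a) != length(b))
    stop(sprintf("length mismatch: %s has %d residues, %s has %d",
                 a$name, length(a), b$name, length(b)))
  idx <- which(a$residues != b$residues)
  mutation_set(idx, a$residues[idx], b$residues[idx])
}

#' Apply a mutation set to a parent variant
#'
#' Each mutation's `from` residue must match the parent at that position;
#' a mismatch aborts with the offending position, which guards against
#' transcription drift between narrative mutation lists and sequence tables.
#'
#' @param parent A `peptide_variant`.
#' @param m A `mutation_set`.
#' @param name Name of the resulting variant.
#' @return A new `peptide_variant` whose `parent` field records the parent's
#'   name. `diff_variants(parent, result)` reproduces `m`.
#' @export
apply_mutations <- function(parent, m, name) {
  stopifnot(inherits(parent, "peptide_variant"), inherits(m, "mutation_set"))
  res <- parent$residues
  for (k in seq_len(nrow(m))) {
    p <- m$position[k]
    if (p < 1L || p > length(res))
      stop(sprintf("mutation position %d outside 1..%d", p, length(res)))
    if (res[p] != m$from[k])
      stop(sprintf("parent '%s' position %d is %s, not %s",
                   parent$name, p, res[p], m$from[k]))
    res[p] <- m$to[k]
  }
  peptide_variant(name, res, c_terminal_amidated = parent$c_terminal_amidated,
                  parent = parent$name, registry = parent$registry)
}

#' Validate a variant against its scaffold
#'
#' Report-only integrity check for knottin variants: sequence length,
#' conservation of the scaffold's cysteine positions (an extended residue
#' whose parent is cysteine also satisfies the check), and a census of
#' extended residues. Disulfide connectivity is not validated: the pairing of
#' the six scaffold cysteines is not part of the model.
#'
#' @param v Variant to check.
#' @param scaffold Reference variant (e.g. the wild-type toxin).
#' @return A list of class `scaffold_report` with elements `length_ok`,
#'   `cysteine_positions`, `cysteine_ok`, `cysteine_mismatches`,
#'   `n_extended`, `extended_positions`.
#' @export
validate_scaffold <- function(v, scaffold) {
  stopifnot(inherits(v, "peptide_variant"), inherits(scaffold, "peptide_variant"))
  reg <- v$registry
  cys_pos <- which(scaffold$residues == "C")
  parent_of <- function(res) {
    m <- match(res, reg$code)
    ifelse(is.na(m), res, reg$parent[m])
  }
  len_ok <- length(v) == length(scaffold)
  cys_ok_vec <- if (len_ok) parent_of(v$residues[cys_pos]) == "C" else logical(0)
  ext_pos <- which(v$residues %in% reg$code)
  structure(list(
    variant = v$name, scaffold = scaffold$name,
    length_ok = len_ok,
    cysteine_positions = cys_pos,
    cysteine_ok = len_ok && all(cys_ok_vec),
    cysteine_mismatches = cys_pos[!cys_ok_vec],
    n_extended = length(ext_pos),
    extended_positions = ext_pos
  ), class = "scaffold_report")
}

#' @export
print.scaffold_report <- function(x, ...) {
  cat(sprintf("<scaffold_report> %s vs %s\n", x$variant, x$scaffold))
  cat(sprintf("  length: %s\n", if (x$length_ok) "ok" else "MISMATCH"))
  cat(sprintf("  cysteines at {%s}: %s\n",
              paste(x$cysteine_positions, collapse = ","),
              if (x$cysteine_ok) "intact"
              else paste("failed at", paste(x$cysteine_mismatches, collapse = ","))))
  cat(sprintf("  extended residues: %d%s\n", x$n_extended,
              if (x$n_extended) paste0(" (positions ",
                                       paste(x$extended_positions, collapse = ","), ")")
              else ""))
  invisible(x)
}

#' Write peptide variants as FASTA with bracketed extended codes
#'
#' There are no standard one-letter codes for the extended residues, so the
#' FASTA export writes them in square brackets (e.g. `...R[norArg]LW...`),
#' keeping sequences machine-readable; [read_fasta_variants()] inverts this.
#'
#' @param variants A list of `peptide_variant` objects.
#' @param path Output file path.
#' @return Invisibly, the lines written.
#' @export
write_fasta_variants <- function(variants, path) {
  lines <- unlist(lapply(variants, function(v) {
    seq <- paste(ifelse(v$residues %in% .CANONICAL_AA, v$residues,
                        paste0("[", v$residues, "]")), collapse = "")
    c(paste0(">", v$name), seq)
  }))
  writeLines(lines, path)
  invisible(lines)
}

#' Read bracketed-FASTA peptide variants
#'
#' @param path Path to a FASTA file written by [write_fasta_variants()].
#' @param registry Extended-residue registry.
#' @return A named list of `peptide_variant` objects.
#' @export
read_fasta_variants <- function(path, registry = extended_residues()) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  out <- list()
  for (k in seq_along(hdr)) {
    name <- sub("^>\\s*", "", lines[hdr[k]])
    to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
    seq <- paste(lines[(hdr[k] + 1L):to], collapse = "")
    toks <- regmatches(seq, gregexpr("\\[[^]]+\\]|.", seq))[[1]]
    res <- ifelse(grepl("^\\[", toks), gsub("\\[|\\]", "", toks), toks)
    out[[name]] <- peptide_variant(name, res, registry = registry)
  }
  out
}
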