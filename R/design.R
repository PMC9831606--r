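#' Read a design-engine scorefile
#'
#' Parses the whitespace-delimited `SCORE:` dialect emitted by protein design
#' engines: every data line starts with a `SCORE:` token, the first such line
#' is the header, and the final column is the design tag (`description`).
#' `total_score` and an interface-energy column (`ddg` by default; lower is
#' better for both) are required. Designed sequences are attached either from
#' a sequence column or from a companion FASTA file keyed by tag.
#'
#' @param path Path to the scorefile (or a character vector of its lines).
#' @param ddg_col Name of the interface-energy column (default `"ddg"`).
#' @param sequence_col Name of an optional sequence column.
#' @param fasta Optional path to a companion FASTA whose record names are
#'   design tags.
#' @return An object of class `design_set`: list with `records` (data.frame
#'   with columns `tag`, `total_score`, `ddg`, `sequence`, plus any extra
#'   numeric columns) and `provenance`.
#' @export
read_scorefile <- function(path, ddg_col = "ddg", sequence_col = "sequence",
                           fasta = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  sc <- grep("^SCORE:", lines)
  if (length(sc) == 0L) stop("no SCORE: lines found")
  toks <- strsplit(trimws(sub("^SCORE:", "", lines[sc])), "\\s+")
  hdr <- toks[[1]]
  for (col in c("total_score", ddg_col, "description")) {
    if (!col %in% hdr) stop("scorefile is missing required column '", col, "'")
  }
  recs <- toks[-1]
  if (length(recs) == 0L) {
    records <- data.frame(tag = character(0), total_score = numeric(0),
                          ddg = numeric(0), sequence = character(0),
                          stringsAsFactors = FALSE)
    return(structure(list(records = records,
                          provenance = paste0("read_scorefile: 0 records")),
                     class = "design_set"))
  }
  bad <- which(vapply(recs, length, 1L) != length(hdr))
  if (length(bad))
    stop(sprintf("scorefile line %d has %d fields, expected %d",
                 sc[bad[1] + 1L], length(recs[[bad[1]]]), length(hdr)))
  m <- do.call(rbind, recs)
  colnames(m) <- hdr
  char_cols <- c("description", if (sequence_col %in% hdr) sequence_col)
  num_cols <- setdiff(hdr, char_cols)
  num <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = length(num_cols), dimnames = list(NULL, num_cols))
  for (col in c("total_score", ddg_col)) {
    nf <- which(!is.finite(num[, col]))
    if (length(nf))
      stop(sprintf("non-finite %s at scorefile line %d", col, sc[nf[1] + 1L]))
  }
  tag <- m[, "description"]
  if (anyDuplicated(tag))
    stop("duplicate design tag(s): ", paste(unique(tag[duplicated(tag)]), collapse = ", "))
  seqs <- if (sequence_col %in% hdr) m[, sequence_col] else NA_character_
  if (!is.null(fasta)) {
    fl <- readLines(fasta)
    h <- grep("^>", fl)
    fn <- sub("^>\\s*", "", fl[h])
    fs <- vapply(seq_along(h), function(k) {
      to <- if (k < length(h)) h[k + 1L] - 1L else length(fl)
      paste(fl[(h[k] + 1L):to], collapse = "")
    }, "")
    seqs <- fs[match(tag, fn)]
  }
  records <- data.frame(tag = tag, total_score = num[, "total_score"],
                        ddg = num[, ddg_col], sequence = seqs,
                        stringsAsFactors = FALSE)
  extras <- setdiff(num_cols, c("total_score", ddg_col))
  for (e in extras) records[[e]] <- num[, e]
  if (!all(is.na(records$sequence))) {
    sl <- nchar(records$sequence[!is.na(records$sequence)])
    if (length(unique(sl)) > 1L) stop("sequences have unequal lengths")
  }
  structure(list(records = records,
                 provenance = sprintf("read_scorefile: %d records", nrow(records))),
            class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat(sprintf("<design_set> %d record(s)\n", nrow(x$records)))
  for (p in x$provenance) cat("  -", p, "\n")
  invisible(x)
}

#' Two-stage design selection cascade
#'
#' Stage 1 keeps the `n_score` records with the lowest `total_score`;
#' stage 2 keeps, among those, the `n_ddg` records with the lowest `ddg`.
#' Ties at either stage are broken by tag in lexicographic order, making the
#' cascade fully reproducible. If the set is no larger than `n_ddg` every
#' record is returned (in cascade order).
#'
#' @param ds A `design_set`.
#' @param n_score Stage-1 size (default 100).
#' @param n_ddg Stage-2 size (default 20).
#' @return A `design_set` with at most `n_ddg` records; provenance records
#'   both stages.
#' @export
select_designs <- function(ds, n_score = 100, n_ddg = 20) {
  stopifnot(inherits(ds, "design_set"))
  if (!(n_score >= n_ddg && n_ddg >= 1))
    stop("need n_score >= n_ddg >= 1")
  r <- ds$records
  o1 <- order(r$total_score, r$tag)
  s1 <- r[o1[seq_len(min(n_score, nrow(r)))], , drop = FALSE]
  o2 <- order(s1$ddg, s1$tag)
  s2 <- s1[o2[seq_len(min(n_ddg, nrow(s1)))], , drop = FALSE]
  rownames(s2) <- NULL
  structure(list(records = s2,
                 provenance = c(ds$provenance,
                                sprintf("stage 1: top %d by total_score", n_score),
                                sprintf("stage 2: top %d by ddg", n_ddg))),
            class = "design_set")
}

#' Position-weight matrix of a sequence set
#'
#' Column frequencies are exact count ratios over the alphabet; the
#' information content of position i is `log2(|alphabet|) - H_i` with `H_i`
#' the Shannon entropy in bits. The optional small-sample correction
#' subtracts the Miller-Madow bias term `(|alphabet| - 1) / (2 ln(2) n)`
#' used by some logo tools (floored at zero); it is off by default.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param alphabet Residue alphabet (default the 20 canonical amino acids).
#' @param small_sample_correction Apply the Miller-Madow correction
#'   (default FALSE).
#' @return An object of class `pwm`: list with `freq` (alphabet x position
#'   matrix), `n_sequences`, `information_content` (bits per position),
#'   `alphabet`.
#' @export
build_pwm <- function(sequences, alphabet = .CANONICAL_AA,
                      small_sample_correction = FALSE) {
  stopifnot(length(sequences) >= 1L)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal lengths")
  chars <- do.call(rbind, strsplit(sequences, ""))
  unknown <- setdiff(unique(as.vector(chars)), alphabet)
  if (length(unknown))
    stop("sequence characters outside the alphabet: ",
         paste(unknown, collapse = ", "))
  alphabet <- sort(alphabet)
  n <- length(sequences)
  freq <- vapply(seq_len(L), function(j)
    tabulate(match(chars[, j], alphabet), length(alphabet)) / n,
    numeric(length(alphabet)))
  freq <- matrix(freq, nrow = length(alphabet),
                 dimnames = list(alphabet, seq_len(L)))
  ent <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- log2(length(alphabet)) - ent
  if (small_sample_correction)
    ic <- pmax(0, ic - (length(alphabet) - 1) / (2 * log(2) * n))
  structure(list(freq = freq, n_sequences = n, information_content = ic,
                 alphabet = alphabet),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d positions over %d-letter alphabet (n = %d)\n",
              ncol(x$freq), length(x$alphabet), x$n_sequences))
  cat("  consensus:", consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' Per-position argmax of the frequency matrix; ties are broken
#' alphabetically (the alphabet is stored sorted, and the first maximum
#' wins).
#'
#' @param p A `pwm`.
#' @return A single consensus string.
#' @export
consensus <- function(p) {
  stopifnot(inherits(p, "pwm"))
  paste(rownames(p$freq)[apply(p$freq, 2, which.max)], collapse = "")
}

#' Write a PWM as CSV
#'
#' @param p A `pwm`.
#' @param path Output path. Rows are positions; columns the alphabet plus
#'   `information_content`.
#' @export
write_pwm <- function(p, path) {
  df <- data.frame(position = seq_len(ncol(p$freq)), t(p$freq),
                   information_content = p$information_content,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Sequence-logo style plot of a PWM
#'
#' Letters stacked per position with heights proportional to
#' frequency x information content (bits), most frequent on top.
#'
#' @param x A `pwm`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.pwm <- function(x, ...) {
  L <- ncol(x$freq)
  ymax <- log2(length(x$alphabet))
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(0, ymax),
                 xlab = "position", ylab = "bits", ...)
  for (j in seq_len(L)) {
    h <- x$freq[, j] * x$information_content[j]
    o <- order(h)
    y0 <- 0
    for (k in o) {
      if (h[k] <= 0) next
      graphics::text(j, y0 + h[k] / 2, rownames(x$freq)[k],
                     cex = max(0.3, min(2, 4 * h[k])), font = 2)
      y0 <- y0 + h[k]
    }
  }
  invisible(x)
}

.RESFILE_COMMANDS <- c("PIKAA", "NATAA", "NOTAA")

#' Design-constraint (resfile) specification
#'
#' A resfile assigns packing/design commands per position: `PIKAA <set>`
#' restricts to the listed residues, `NATAA` keeps the native identity
#' (repack only), `NOTAA <set>` disallows the listed residues. Default
#' commands before the `start` marker apply to every position without an
#' explicit body command.
#'
#' @param default Named list with `command` and `args` for the default
#'   command block.
#' @param positions data.frame with columns `resnum`, `chain`, `command`,
#'   `args` (one row per position command; `args` is `""` for `NATAA`).
#' @return An object of class `resfile_spec`.
#' @export
resfile_spec <- function(default = list(command = "PIKAA",
                                        args = paste(.CANONICAL_AA, collapse = "")),
                         positions = data.frame(resnum = integer(0),
                                                chain = character(0),
                                                command = character(0),
                                                args = character(0),
                                                stringsAsFactors = FALSE)) {
  stopifnot(default$command %in% .RESFILE_COMMANDS || identical(default$command, "NATAA"))
  if (default$command %in% c("PIKAA", "NOTAA") && !nzchar(default$args))
    stop(default$command, " requires a non-empty residue set")
  if (nrow(positions)) {
    bad <- !positions$command %in% .RESFILE_COMMANDS
    if (any(bad)) stop("unknown resfile command: ", positions$command[bad][1])
    need <- positions$command %in% c("PIKAA", "NOTAA") & !nzchar(positions$args)
    if (any(need)) stop("PIKAA/NOTAA position commands require a residue set")
    if (anyDuplicated(paste(positions$resnum, positions$chain)))
      stop("duplicate position command")
  }
  rownames(positions) <- NULL
  structure(list(default = default, positions = positions),
            class = "resfile_spec")
}

#' Parse a resfile
#'
#' Accepts the dialect: optional default command lines, then a `start`
#' marker, then body lines `<resnum> <chain> <COMMAND> [args]`.
#'
#' @param text Path to a resfile or a character vector of lines.
#' @return A [resfile_spec()].
#' @export
parse_resfile <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text) else text
  lines <- trimws(lines)
  start <- which(tolower(lines) == "start")
  if (length(start) != 1L) stop("resfile must contain exactly one 'start' marker")
  default <- list(command = "NATAA", args = "")
  for (ln in seq_len(start - 1L)) {
    if (!nzchar(lines[ln]) || grepl("^#", lines[ln])) next
    tk <- strsplit(lines[ln], "\\s+")[[1]]
    if (grepl("^[0-9]+$", tk[1]))
      stop(sprintf("resfile line %d: body line before 'start'", ln))
    if (!tk[1] %in% .RESFILE_COMMANDS)
      stop(sprintf("resfile line %d: unknown command token '%s'", ln, tk[1]))
    default <- list(command = tk[1],
                    args = if (length(tk) > 1L) paste(tk[-1], collapse = "") else "")
  }
  res <- list()
  for (ln in seq(start + 1L, length.out = length(lines) - start)) {
    if (!nzchar(lines[ln]) || grepl("^#", lines[ln])) next
    tk <- strsplit(lines[ln], "\\s+")[[1]]
    if (length(tk) < 3L || !grepl("^[0-9]+$", tk[1]))
      stop(sprintf("resfile line %d: expected '<resnum> <chain> <COMMAND> [args]'", ln))
    if (!tk[3] %in% .RESFILE_COMMANDS)
      stop(sprintf("resfile line %d: unknown command token '%s'", ln, tk[3]))
    res[[length(res) + 1L]] <- data.frame(
      resnum = as.integer(tk[1]), chain = tk[2], command = tk[3],
      args = if (length(tk) > 3L) paste(tk[-(1:3)], collapse = "") else "",
      stringsAsFactors = FALSE)
  }
  positions <- if (length(res)) do.call(rbind, res) else
    data.frame(resnum = integer(0), chain = character(0),
               command = character(0), args = character(0),
               stringsAsFactors = FALSE)
  resfile_spec(default = default, positions = positions)
}

#' Write a resfile
#'
#' `parse_resfile(write_resfile(spec))` is the identity up to whitespace.
#'
#' @param spec A [resfile_spec()].
#' @param path Optional output path; when NULL the lines are returned.
#' @return The resfile lines, invisibly when `path` is given.
#' @export
write_resfile <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "resfile_spec"))
  head_line <- trimws(paste(spec$default$command, spec$default$args))
  body <- if (nrow(spec$positions))
    trimws(sprintf("%d %s %s %s", spec$positions$resnum, spec$positions$chain,
                   spec$positions$command, spec$positions$args))
  else character(0)
  lines <- c(head_line, "start", body)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @export
print.resfile_spec <- function(x, ...) {
  tab <- table(factor(x$positions$command, levels = .RESFILE_COMMANDS))
  cat(sprintf("<resfile_spec> default %s %s; %d position command(s) (%s)\n",
              x$default$command, x$default$args, nrow(x$positions),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Derive design constraints from a contact profile
#'
#' Encodes the constraint policy of a membrane-interface design round as a
#' resfile: positions fixed to repack-only get `NATAA`; positions fixed to a
#' single identity get `PIKAA <residue>`; positions whose combined lipid
#' (head + tail) fractional contact reaches `lipid_threshold` and are not
#' otherwise constrained are stripped of acidic residues via
#' `NOTAA <disallow>`; scaffold cysteines get `NATAA` so the disulfide
#' scaffold is never designed away; everything else falls to the default
#' `PIKAA` over the full canonical alphabet.
#'
#' @param profile A `contact_profile` covering all peptide positions.
#' @param fixed_nataa Integer positions held at their native identity.
#' @param fixed_identity Named character vector, names = positions, values =
#'   the single allowed residue (e.g. `c("20" = "R")`).
#' @param disallow Residues disallowed at lipid-facing positions (default
#'   the acidic residues `E`, `D`).
#' @param lipid_threshold Fraction of observations in `(0, 1]` above which a
#'   position counts as lipid-facing (default 0.25).
#' @param scaffold_cys Positions of scaffold cysteines, repack-only by
#'   default; pass `integer(0)` to leave them at the default command.
#' @param chain Chain letter for the body lines (default `"E"`).
#' @return A [resfile_spec()].
#' @export
derive_constraints <- function(profile, fixed_nataa = integer(0),
                               fixed_identity = character(0),
                               disallow = c("E", "D"),
                               lipid_threshold = 0.25,
                               scaffold_cys = c(2, 9, 15, 16, 21, 25),
                               chain = "E") {
  stopifnot(inherits(profile, "contact_profile"))
  if (!(lipid_threshold > 0 && lipid_threshold <= 1))
    stop("lipid_threshold must lie in (0, 1]")
  pos <- profile$positions
  fixed_id_pos <- as.integer(names(fixed_identity))
  conflict <- intersect(fixed_id_pos, c(fixed_nataa, scaffold_cys))
  if (length(conflict))
    stop("position(s) ", paste(conflict, collapse = ","),
         " have conflicting fixed-identity and repack-only commands")
  lipid <- rowSums(profile$values[, intersect(c("lipid_head", "lipid_tail"),
                                              colnames(profile$values)),
                                  drop = FALSE])
  nataa_pos <- sort(unique(c(as.integer(fixed_nataa), as.integer(scaffold_cys))))
  nataa_pos <- intersect(nataa_pos, pos)
  lipid_pos <- pos[lipid >= lipid_threshold]
  lipid_pos <- setdiff(lipid_pos, c(nataa_pos, fixed_id_pos))
  rows <- rbind(
    if (length(nataa_pos))
      data.frame(resnum = nataa_pos, chain = chain, command = "NATAA",
                 args = "", stringsAsFactors = FALSE),
    if (length(fixed_id_pos))
      data.frame(resnum = sort(fixed_id_pos), chain = chain, command = "PIKAA",
                 args = unname(fixed_identity[order(fixed_id_pos)]),
                 stringsAsFactors = FALSE),
    if (length(lipid_pos))
      data.frame(resnum = sort(lipid_pos), chain = chain, command = "NOTAA",
                 args = paste(disallow, collapse = ""),
                 stringsAsFactors = FALSE)
  )
  if (is.null(rows))
    rows <- data.frame(resnum = integer(0), chain = character(0),
                       command = character(0), args = character(0),
                       stringsAsFactors = FALSE)
  resfile_spec(default = list(command = "PIKAA",
                              args = paste(.CANONICAL_AA, collapse = "")),
               positions = rows)
}
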