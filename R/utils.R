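#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching how percent
#' metrics are conventionally printed in ephys tables (`round()` in base R
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible sub-seed for a named generator stream
#'
#' One top-level seed fans out to independent per-generator substreams keyed
#' by a stream label, so adding a generator to a simulation does not perturb
#' the draws of the others. The derivation is a fixed integer hash; it stays
#' within 32-bit integer range.
#'
#' @param seed Integer top-level seed.
#' @param stream Character label of the substream (e.g. `"scorefile"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  cp <- utf8ToInt(stream)
  h <- sum(cp * seq_along(cp)) %% 999983
  as.integer((abs(as.numeric(seed)) %% 2147480000 * 31 + h * 7919) %% 2147483647)
}

# Squared distances between rows a[i, ] and b[j, ] for index pairs (i, j).
# Both search methods funnel through this kernel so their results are
# bit-identical on the pairs they agree to test.
.pair_dist2 <- function(a, b, i, j) {
  d <- a[i, , drop = FALSE] - b[j, , drop = FALSE]
  rowSums(d * d)
}

#' Find all atom pairs within a distance cutoff
#'
#' Returns every pair (i, j) with `|a[i,] - b[j,]| <= cutoff`. The default
#' `"cell"` method bins the second point set into a uniform grid with edge
#' length `cutoff` and only tests candidates from the 27 neighbouring cells;
#' it is guaranteed to return exactly the same pairs as the `"brute"`
#' all-pairs search because both evaluate the same distance kernel.
#'
#' @param a,b Numeric matrices with 3 columns (x, y, z coordinates in
#'   Angstrom).
#' @param cutoff Distance cutoff in Angstrom.
#' @param method `"cell"` (spatial index, default) or `"brute"` (all pairs).
#' @return A data.frame with columns `i`, `j`, `dist`, sorted by `dist`.
#' @export
pairs_within <- function(a, b, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, cutoff > 0)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  if (method == "brute") {
    i <- rep(seq_len(nrow(a)), times = nrow(b))
    j <- rep(seq_len(nrow(b)), each = nrow(a))
  } else {
    org <- pmin(apply(a, 2, min), apply(b, 2, min))
    keyfun <- function(m) {
      cl <- floor(sweep(m, 2, org) / cutoff)
      paste(cl[, 1], cl[, 2], cl[, 3], sep = ",")
    }
    bcell <- floor(sweep(b, 2, org) / cutoff)
    bkey <- paste(bcell[, 1], bcell[, 2], bcell[, 3], sep = ",")
    bmap <- split(seq_len(nrow(b)), bkey)
    acell <- floor(sweep(a, 2, org) / cutoff)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    ii <- jj <- vector("list", nrow(a))
    for (k in seq_len(nrow(a))) {
      nb <- sweep(off, 2, as.numeric(acell[k, ]), "+")
      keys <- paste(nb[, 1], nb[, 2], nb[, 3], sep = ",")
      cand <- unlist(bmap[keys], use.names = FALSE)
      if (length(cand)) {
        ii[[k]] <- rep.int(k, length(cand))
        jj[[k]] <- cand
      }
    }
    i <- unlist(ii, use.names = FALSE)
    j <- unlist(jj, use.names = FALSE)
    if (is.null(i)) i <- integer(0)
    if (is.null(j)) j <- integer(0)
  }
  if (length(i) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  d2 <- .pair_dist2(a, b, i, j)
  keep <- d2 <= cutoff * cutoff
  out <- data.frame(i = i[keep], j = j[keep], dist = sqrt(d2[keep]))
  out <- out[order(out$dist, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE if any pair of rows from a and b lies within cutoff.
.any_within <- function(a, b, cutoff, method = "cell") {
  nrow(pairs_within(a, b, cutoff, method = method)) > 0L
}
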