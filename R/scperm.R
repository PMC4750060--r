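#' Signed circular permutations
#'
#' A signed circular permutation represents the order and orientation of
#' locally collinear blocks (LCBs) around a circular genome such as a
#' plastome. Each block id appears exactly once, signed by its strand.
#' Two permutations are considered equal when they coincide after rotation
#' and/or whole-circle reflection (reading the circle backwards with all
#' signs flipped); [canonicalize()] produces the unique normal form in
#' which the smallest block id comes first with positive sign.
#'
#' Block ids may be any distinct positive integers (they need not be
#' 1..n), so that published LCB numberings can be used directly; they are
#' rank-mapped internally wherever contiguous ids are required.
#'
#' @param blocks integer vector of signed block ids; each absolute id
#'   distinct and non-zero.
#' @return An object of class `scperm` (an integer vector).
#' @examples
#' p <- scperm(c(2, 3, 1))
#' canonicalize(p)            # (+1 +2 +3)
#' canonicalize(scperm(c(-3, -2, -1)))  # also (+1 +2 +3)
#' @export
scperm <- function(blocks) {
  blocks <- as.integer(blocks)
  if (length(blocks) < 1L || anyNA(blocks) || any(blocks == 0L))
    stop("blocks must be a non-empty vector of non-zero signed integers")
  dup <- unique(abs(blocks)[duplicated(abs(blocks))])
  if (length(dup))
    stop("duplicate block id(s): ", paste(dup, collapse = ", "))
  structure(blocks, class = "scperm")
}

#' @export
print.scperm <- function(x, ...) {
  cat("<scperm> (",
      paste(ifelse(x > 0, paste0("+", x), as.character(x)), collapse = " "),
      ")\n", sep = "")
  invisible(x)
}

rotate_vec <- function(v, k) {
  if (k == 1L) v else c(v[k:length(v)], v[seq_len(k - 1L)])
}

#' Canonical form of a signed circular permutation
#'
#' Rotates and, if necessary, reflects the circle so that the block with
#' the smallest id comes first with positive sign. Idempotent; two
#' permutations are circularly equal iff their canonical forms are
#' identical vectors.
#'
#' @param p an [scperm].
#' @return An [scperm] in canonical form.
#' @export
canonicalize <- function(p) {
  v <- as.integer(p)
  m <- min(abs(v))
  k <- match(m, abs(v))
  if (v[k] < 0L) {
    v <- rev(-v)
    k <- match(m, abs(v))
  }
  scperm(rotate_vec(v, k))
}

#' Apply an inversion to a signed circular permutation
#'
#' Junctions are indexed `0..n` on the current linearization of the circle
#' (junction `k` lies after the block at position `k`; junctions 0 and n
#' are the same circular junction, the wrap point). The inversion cuts at
#' junctions `i < j`, reverses the enclosed segment (positions `i+1..j`)
#' and flips its signs. Inverting the complement of a segment yields the
#' same circular permutation up to reflection, so restricting `j - i < n`
#' loses no generality.
#'
#' @param p an [scperm].
#' @param i,j cut junctions, `0 <= i < j <= n`, not both the wrap point
#'   (`(0, n)` would invert the whole circle, a no-op up to reflection).
#' @return The inverted [scperm] (same linear frame as the input).
#' @examples
#' apply_inversion(scperm(1:4), 1, 3)  # (+1 -3 -2 +4)
#' @export
apply_inversion <- function(p, i, j) {
  n <- length(p)
  if (!(i >= 0L && j > i && j <= n))
    stop("cut junctions must satisfy 0 <= i < j <= n")
  if (i == 0L && j == n)
    stop("inverting the whole circle is the identity; pick a proper segment")
  v <- as.integer(p)
  seg <- (i + 1L):j
  v[seg] <- rev(-v[seg])
  scperm(v)
}

# Relabel p so that q becomes the (positive, ascending) identity:
# block at position k of q (with sign s) is renamed to s*k.  Reversal
# distance is invariant under this renaming, so d(p, q) = d(relabel, id).
relabel_to_identity <- function(p, q) {
  if (length(p) != length(q) || !setequal(abs(p), abs(q)))
    stop("permutations must share the same block set")
  k <- match(abs(p), abs(q))
  scperm(sign(as.integer(p)) * sign(as.integer(q)[k]) * k)
}

# All distinct inversions of an n-block circle, as a 2-column matrix of
# junction pairs (i, j).  Complementary segments are reflections of each
# other and therefore circularly equal; enumerating non-wrapping segments
# covers every inversion up to canonical equality.
all_inversions <- function(n) {
  out <- matrix(0L, nrow = (n + 1L) * n / 2L - 1L, ncol = 2L)
  r <- 0L
  for (i in 0L:(n - 1L)) for (j in (i + 1L):n) {
    if (i == 0L && j == n) next
    r <- r + 1L
    out[r, ] <- c(i, j)
  }
  out[seq_len(r), , drop = FALSE]
}

#' Read and write GRIMM-style permutation files
#'
#' The GRIMM text format holds one genome per record: a `>name` header
#' line followed by whitespace-separated signed integers, optionally
#' terminated by `$`.
#'
#' @param path file path.
#' @return `read_grimm`: a named list of [scperm] objects.
#' @export
read_grimm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  cur <- NULL
  buf <- character()
  flush <- function() {
    if (is.null(cur)) return()
    toks <- unlist(strsplit(paste(buf, collapse = " "), "[[:space:]]+"))
    toks <- toks[nzchar(toks) & toks != "$"]
    out[[cur]] <<- scperm(as.integer(toks))
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur <- trimws(sub("^>", "", ln))
      buf <- character()
    } else {
      if (is.null(cur)) stop("malformed GRIMM file: data before first '>' header")
      buf <- c(buf, ln)
    }
  }
  flush()
  out
}

#' @param perms named list of [scperm] objects.
#' @rdname read_grimm
#' @export
write_grimm <- function(perms, path) {
  if (is.null(names(perms)) || any(!nzchar(names(perms))))
    names(perms) <- paste0("genome", seq_along(perms))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(perms)) {
    writeLines(paste0(">", nm), con)
    writeLines(paste(c(as.integer(perms[[nm]]), "$"), collapse = " "), con)
  }
  invisible(path)
}
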