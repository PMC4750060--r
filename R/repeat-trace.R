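# Tracing oriented repeat copies through inversion scenarios on block
# arrangements. Repeat copies (e.g. the duplicated trnQ-UUG gene of
# cupressophyte plastomes) are zero-length oriented markers that either
# sit in the spacer at a block junction or ride inside a block; an
# inversion whose cut point falls between two tandem copies carries one
# copy away with the segment and flips it, turning a tandem repeat into
# a dispersed inverted repeat.

#' Construct a repeat configuration
#'
#' A circular arrangement of signed blocks interleaved with oriented
#' repeat copies.
#'
#' @param perm an [scperm] giving the block order (the stored linear
#'   frame is the frame in which junctions are indexed).
#' @param copies list of copies. Each copy is a list with `label`
#'   (string), `orient` (`"+"`/`"-"`) and an anchor: either
#'   `junction = <k>` placing the copy in the gap after the block at
#'   position `k` (`1..n`; junction `n` wraps to position 1), with
#'   copies at one junction ordered as given; or `block = <position>`
#'   with `offset` in `[0, 1]`, placing the copy inside the block at
#'   that position.
#' @return An object of class `repeat_config`.
#' @export
repeat_config <- function(perm, copies = list()) {
  n <- length(perm)
  blocks <- lapply(seq_len(n), function(k)
    list(id = as.integer(perm)[k], internal = list()))
  jcopies <- rep(list(list()), n)
  for (cp in copies) {
    stopifnot(!is.null(cp$label), cp$orient %in% c("+", "-"))
    if (!is.null(cp$junction)) {
      k <- cp$junction
      if (!(k %in% seq_len(n))) stop("junction out of range: ", k)
      jcopies[[k]][[length(jcopies[[k]]) + 1L]] <-
        list(label = cp$label, orient = cp$orient)
    } else if (!is.null(cp$block)) {
      k <- cp$block
      if (!(k %in% seq_len(n))) stop("block position out of range: ", k)
      off <- if (is.null(cp$offset)) 0.5 else cp$offset
      blocks[[k]]$internal[[length(blocks[[k]]$internal) + 1L]] <-
        list(label = cp$label, orient = cp$orient, offset = off)
    } else stop("copy needs a 'junction' or 'block' anchor")
  }
  structure(list(blocks = blocks, jcopies = jcopies),
            class = "repeat_config")
}

#' @export
print.repeat_config <- function(x, ...) {
  n <- length(x$blocks)
  parts <- character(0)
  for (k in seq_len(n)) {
    b <- x$blocks[[k]]
    lab <- if (b$id > 0) paste0("+", b$id) else as.character(b$id)
    if (length(b$internal))
      lab <- paste0(lab, "{", paste(vapply(b$internal, function(cp)
        paste0(cp$label, cp$orient), character(1)), collapse = ","), "}")
    parts <- c(parts, lab)
    for (cp in x$jcopies[[k]])
      parts <- c(parts, paste0("[", cp$label, cp$orient, "]"))
  }
  cat("<repeat_config> (", paste(parts, collapse = " "), ")\n", sep = "")
  invisible(x)
}

config_perm <- function(config) {
  scperm(vapply(config$blocks, function(b) b$id, integer(1)))
}

# flat copy table: label, orient, anchor type, position
config_copies <- function(config) {
  out <- data.frame(label = character(), orient = character(),
                    anchor = character(), at = integer(),
                    slot = integer(), stringsAsFactors = FALSE)
  for (k in seq_along(config$blocks)) {
    for (cp in config$blocks[[k]]$internal)
      out[nrow(out) + 1L, ] <- list(cp$label, cp$orient, "block", k, NA_integer_)
    for (s in seq_along(config$jcopies[[k]]))
      out[nrow(out) + 1L, ] <- list(config$jcopies[[k]][[s]]$label,
                                    config$jcopies[[k]][[s]]$orient,
                                    "junction", k, s)
  }
  out
}

flip_copy <- function(cp) {
  cp$orient <- if (cp$orient == "+") "-" else "+"
  cp
}

#' Apply an inversion to a repeat configuration
#'
#' Junctions are indexed as in [apply_inversion()] (`0..n` on the stored
#' linearization; `0` and `n` are the wrap point). When a cut junction
#' hosts `m` repeat copies there are `m + 1` gaps to cut in; `cut_slots`
#' chooses the gap at each endpoint (`0` = before all copies, `m` =
#' after all). By default the gap nearest the inverted segment is cut,
#' so junction copies stay outside the segment. Blocks and copies inside
#' the segment are order-reversed and orientation-flipped; copy number
#' is always conserved.
#'
#' @param config a [repeat_config()].
#' @param i,j cut junctions, `0 <= i < j <= n`, `(0, n)` excluded.
#' @param cut_slots integer vector `c(left, right)`; `NA` picks the
#'   default gap.
#' @return The inverted `repeat_config`.
#' @export
apply_inversion_traced <- function(config, i, j, cut_slots = c(NA, NA)) {
  n <- length(config$blocks)
  if (!(i >= 0L && j > i && j <= n))
    stop("cut junctions must satisfy 0 <= i < j <= n")
  if (i == 0L && j == n)
    stop("inverting the whole circle is the identity; pick a proper segment")
  ji <- if (i == 0L) n else i     # stored index of the left cut junction
  mi <- length(config$jcopies[[ji]])
  mj <- length(config$jcopies[[j]])
  si <- cut_slots[1]
  sj <- cut_slots[2]
  if (is.na(si)) si <- mi         # default: copies stay left of the cut
  if (is.na(sj)) sj <- 0L         # default: copies stay right of the cut
  if (si < 0L || si > mi) stop("invalid left cut slot ", si, " (junction hosts ",
                               mi, " copies)")
  if (sj < 0L || sj > mj) stop("invalid right cut slot ", sj, " (junction hosts ",
                               mj, " copies)")

  # items inside the segment, in order: junction-i copies after slot si,
  # blocks i+1..j, junction-j copies up to slot sj
  jci <- config$jcopies[[ji]]
  jcj <- config$jcopies[[j]]
  seg <- list()
  if (mi > si) for (s in (si + 1L):mi)
    seg[[length(seg) + 1L]] <- list(type = "copy", copy = jci[[s]])
  for (k in (i + 1L):j) {
    seg[[length(seg) + 1L]] <- list(type = "block", block = config$blocks[[k]])
    if (k < j) {
      for (cp in config$jcopies[[k]])
        seg[[length(seg) + 1L]] <- list(type = "copy", copy = cp)
    }
  }
  if (sj > 0L) for (s in seq_len(sj))
    seg[[length(seg) + 1L]] <- list(type = "copy", copy = jcj[[s]])

  # invert the segment
  seg <- rev(seg)
  seg <- lapply(seg, function(it) {
    if (it$type == "block") {
      b <- it$block
      b$id <- -b$id
      b$internal <- lapply(rev(b$internal), function(cp) {
        cp <- flip_copy(cp)
        cp$offset <- 1 - cp$offset
        cp
      })
      it$block <- b
    } else {
      it$copy <- flip_copy(it$copy)
    }
    it
  })

  # reassemble: prefix (up to slot si of junction ji), segment, suffix
  items <- list()
  push_block <- function(b) items[[length(items) + 1L]] <<- list(type = "block", block = b)
  push_copy <- function(cp) items[[length(items) + 1L]] <<- list(type = "copy", copy = cp)
  for (k in seq_len(i)) {       # blocks 1..i with their junction copies
    push_block(config$blocks[[k]])
    if (k < i) for (cp in config$jcopies[[k]]) push_copy(cp)
  }
  if (i > 0L) for (s in seq_len(si)) push_copy(jci[[s]])
  for (it in seg) items[[length(items) + 1L]] <- it
  if (mj > sj) for (s in (sj + 1L):mj) push_copy(jcj[[s]])
  if (j < n) for (k in (j + 1L):n) {
    push_block(config$blocks[[k]])
    if (k < n) for (cp in config$jcopies[[k]]) push_copy(cp)
  }
  # wrap-point copies: when i > 0 the junction-n copies were untouched
  if (i > 0L) for (cp in config$jcopies[[n]]) push_copy(cp)
  # when i == 0 the untouched prefix of junction n's copies (slots 1..si)
  # stays at the wrap point, i.e. at the very end of the linearization
  if (i == 0L && si > 0L) for (s in seq_len(si)) push_copy(jci[[s]])

  items_to_config(items)
}

items_to_config <- function(items) {
  # rotate so the list starts with a block
  first_b <- which(vapply(items, function(it) it$type == "block", logical(1)))[1]
  if (is.na(first_b)) stop("configuration must contain at least one block")
  if (first_b > 1L)
    items <- c(items[first_b:length(items)], items[seq_len(first_b - 1L)])
  blocks <- list()
  jcopies <- list()
  for (it in items) {
    if (it$type == "block") {
      blocks[[length(blocks) + 1L]] <- it$block
      jcopies[[length(blocks)]] <- list()
    } else {
      k <- length(blocks)
      jcopies[[k]][[length(jcopies[[k]]) + 1L]] <- it$copy
    }
  }
  structure(list(blocks = blocks, jcopies = jcopies), class = "repeat_config")
}

#' Trace a repeat configuration through an inversion scenario
#'
#' @param config a [repeat_config()].
#' @param scenario a list of steps, each `list(i =, j =, slots = c(l, r))`
#'   (slots optional), or an `inversion_scenario` from
#'   [sort_by_reversals()] (default slots apply).
#' @return List of `repeat_config` objects: the input, one per step, the
#'   final state last (`length(scenario) + 1` entries).
#' @export
trace_scenario <- function(config, scenario) {
  out <- list(config)
  for (st in scenario) {
    if (is.numeric(st)) st <- list(i = st[[1L]], j = st[[2L]])
    slots <- if (!is.null(st$slots)) st$slots else c(NA, NA)
    config <- apply_inversion_traced(config, st$i, st$j, slots)
    out[[length(out) + 1L]] <- config
  }
  out
}

#' Classify the arrangement of repeat copies
#'
#' Pure function of the configuration, for copies whose label starts
#' with `label_prefix`: two copies with no intervening block are
#' adjacent (same junction); same orientation adjacent copies form a
#' `tandem_forward` pair, opposite ones `adjacent_inverted`; separated
#' copies are `dispersed_forward` or `dispersed_inverted` (the short
#' inverted repeat, sIR, of conifer plastomes); one copy is `single`;
#' three or more copies give `multi_copy_mixed` with a per-pair
#' sub-report in attribute `pairs`.
#'
#' @param config a [repeat_config()].
#' @param label_prefix copies whose label starts with this string are
#'   considered (default "" = all).
#' @return Character scalar classification.
#' @export
classify_arrangement <- function(config, label_prefix = "") {
  tab <- config_copies(config)
  tab <- tab[startsWith(tab$label, label_prefix), , drop = FALSE]
  if (!nrow(tab)) stop("no copies matching prefix '", label_prefix, "'")
  if (nrow(tab) == 1L) return("single")
  pair_relation <- function(a, b) {
    adjacent <- tab$anchor[a] == "junction" && tab$anchor[b] == "junction" &&
      tab$at[a] == tab$at[b]
    same <- tab$orient[a] == tab$orient[b]
    if (adjacent && same) "tandem_forward"
    else if (adjacent) "adjacent_inverted"
    else if (same) "dispersed_forward"
    else "dispersed_inverted"
  }
  if (nrow(tab) == 2L) return(pair_relation(1L, 2L))
  pairs <- data.frame(a = character(), b = character(), relation = character(),
                      stringsAsFactors = FALSE)
  for (a in seq_len(nrow(tab) - 1L)) for (b in (a + 1L):nrow(tab))
    pairs[nrow(pairs) + 1L, ] <- list(tab$label[a], tab$label[b],
                                      pair_relation(a, b))
  structure("multi_copy_mixed", pairs = pairs)
}

#' Count distinct repeat loci
#'
#' Number of distinct anchors (junctions or blocks) hosting at least one
#' matching copy; adjacent copies at one junction count as a single
#' locus (a tandem array is one locus).
#'
#' @inheritParams classify_arrangement
#' @return Integer count.
#' @export
count_repeat_loci <- function(config, label_prefix = "") {
  tab <- config_copies(config)
  tab <- tab[startsWith(tab$label, label_prefix), , drop = FALSE]
  length(unique(paste(tab$anchor, tab$at)))
}

#' Orientation pattern of matching copies
#'
#' @inheritParams classify_arrangement
#' @return Character vector of copy orientations in circle order.
#' @export
copy_orientations <- function(config, label_prefix = "") {
  tab <- config_copies(config)
  tab$orient[startsWith(tab$label, label_prefix)]
}

# ---------------------------------------------------------------------------
# Worked fixtures: the narrated trnQ-UUG scenarios.  Block ids follow the
# published 33-LCB numbering for the blocks the narration names (1, 2,
# 11, 12, 25, 29); unnamed intervening stretches are collapsed into
# single filler blocks, which leaves every narrated cut point and trnQ
# placement well-defined.

#' trnQ-UUG repeat fixtures and narrated inversion scenarios
#'
#' `trnq_config_sciadopitys()`: the tandem trnQ-UUG pair in the spacer
#' between LCB 25 and LCB 1 (both copies forward), with LCB 29 and LCB 2
#' placed so that the narrated inversions are expressible; filler block
#' 31 stands for the stretch between LCB 1 and 29, filler 32 for the one
#' after LCB 11.
#'
#' `trnq_scenario_to_taxus()`: two inversions. First, between LCB 29 and
#' LCB 1: the segment carrying the tandem pair and LCB 1 is inverted,
#' bringing LCB 1 next to LCB 2 and leaving the gene order
#' LCB2 - trnQ - trnQ - LCB1. Second, between LCB 1 and LCB 11 with the
#' cut in the gap between the two copies: one copy rides with LCB 1, the
#' other with LCB 2, splitting the tandem pair into a dispersed inverted
#' repeat with one copy near LCB 2 (rps16/chlB side) and one near LCB 1
#' (psbK/psbI side).
#'
#' `trnq_config_a25()` / `trnq_scenario_to_cunninghamia()`: the ancestor
#' of Cupressaceae carries the tandem pair between LCB 1 and LCB 12 plus
#' a third copy inside LCB 2; one inversion cut between the pair and at
#' the LCB 12 / LCB 29 junction leaves copies associated with LCB 1,
#' LCB 12 and LCB 2 - two forward, one inverted.
#'
#' @return A [repeat_config()] or a scenario list for [trace_scenario()].
#' @name trnq_fixtures
NULL

#' @rdname trnq_fixtures
#' @export
trnq_config_sciadopitys <- function() {
  repeat_config(
    scperm(c(25, 1, 31, 29, 2, 11, 32)),
    copies = list(
      list(label = "trnQ-UUG#1", orient = "+", junction = 1L),
      list(label = "trnQ-UUG#2", orient = "+", junction = 1L)))
}

#' @rdname trnq_fixtures
#' @export
trnq_scenario_to_taxus <- function() {
  list(
    # between LCB 29 and 1; the tandem pair rides with LCB 1
    list(i = 1L, j = 4L, slots = c(0L, NA)),
    # between LCB 1 and 11; cut in the gap between the two copies
    list(i = 4L, j = 6L, slots = c(1L, NA)))
}

#' @rdname trnq_fixtures
#' @export
trnq_config_a25 <- function() {
  repeat_config(
    scperm(c(1, 12, 29, 2, 33)),
    copies = list(
      list(label = "trnQ-UUG#1", orient = "+", junction = 1L),
      list(label = "trnQ-UUG#2", orient = "+", junction = 1L),
      list(label = "trnQ-UUG#3", orient = "+", block = 4L, offset = 0.5)))
}

#' @rdname trnq_fixtures
#' @export
trnq_scenario_to_cunninghamia <- function() {
  list(
    # between LCB 12 and 29, cutting the gap between the two copies
    list(i = 1L, j = 2L, slots = c(1L, NA)))
}

# blocks flanking each matching copy (junction copies), or the host
# block (internal copies); used to express "near gene X" checks
copy_neighbourhoods <- function(config, label_prefix = "") {
  n <- length(config$blocks)
  ids <- vapply(config$blocks, function(b) b$id, integer(1))
  out <- list()
  for (k in seq_len(n)) {
    for (cp in config$blocks[[k]]$internal) {
      if (startsWith(cp$label, label_prefix))
        out[[cp$label]] <- list(kind = "internal", blocks = abs(ids[k]),
                                orient = cp$orient)
    }
    for (cp in config$jcopies[[k]]) {
      if (startsWith(cp$label, label_prefix)) {
        nxt <- if (k == n) 1L else k + 1L
        out[[cp$label]] <- list(kind = "junction",
                                blocks = abs(c(ids[k], ids[nxt])),
                                orient = cp$orient)
      }
    }
  }
  out
}
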