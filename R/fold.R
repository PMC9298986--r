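#' Fold a short RNA into its minimum-free-energy single hairpin
#'
#' Computes, by dynamic programming, the minimum-energy secondary structure
#' among all nested structures containing exactly one terminal loop: a chain
#' of nested base pairs whose helices may be interrupted by bulges and
#' internal loops, but with no multibranch loops. This restriction matches
#' the stem-loop geometry of microRNA precursors and keeps an exhaustive
#' enumeration oracle tractable for testing.
#'
#' The energy of a structure is the sum of nearest-neighbor stacking terms,
#' loop penalties (hairpin, bulge, internal; logarithmic in loop size), and a
#' terminal penalty for an AU/GU outermost pair. Interior loops longer than
#' `model$max_interior` nucleotides on either side are disallowed. The empty
#' structure scores 0, so the reported MFE is always `<= 0`. Ties are broken
#' deterministically: more pairs first, then the outermost pair with the
#' smallest opening position, then the stacked continuation.
#'
#' @param seq RNA sequence (a single string over `A/C/G/U`; `T` is accepted
#'   and converted). Length must be between `min_loop + 2` and 300.
#' @param model An `energy_model`; defaults to the packaged model.
#' @return An object of class `hairpin_structure`: a list with `sequence`,
#'   `dotbracket`, `pairs` (two-column matrix of 1-based positions, outermost
#'   first), `mfe` and `model`.
#' @examples
#' hp <- fold_hairpin("GGGGAAACCCC")
#' hp$mfe
#' hp$dotbracket
#' @seealso [is_stable()], [structure_energy()]
#' @export
fold_hairpin <- function(seq, model = default_energy_model()) {
  stopifnot(length(seq) == 1, is.character(seq))
  seq <- as_rna(seq, allow_n = FALSE)
  n <- nchar(seq)
  if (n < model$min_loop + 2 || n > 300) {
    stop("fold_hairpin: sequence length must be between ",
         model$min_loop + 2, " and 300 nt (got ", n, ")")
  }
  codes <- match(seq_chars(seq), RNA_BASES) - 1L
  K <- as.integer(model$max_interior)
  hp <- vapply(0:n, function(l) {
    v <- hairpin_penalty(model, l); if (is.finite(v)) v else Inf
  }, numeric(1))
  bp <- vapply(0:n, function(l) {
    v <- bulge_penalty(model, l); if (is.finite(v)) v else Inf
  }, numeric(1))
  ip <- outer(0:K, 0:K, function(a, b) internal_penalty(model, a, b))
  ip[!is.finite(ip)] <- Inf
  ep <- end_penalty(model, PAIR_NAMES)
  res <- fold_hairpin_cpp(codes, model$stacks, hp, bp, ip,
                          as.integer(model$min_loop), K, ep)
  pairs <- res$pairs
  storage.mode(pairs) <- "integer"
  new_hairpin_structure(seq, pairs, res$mfe, model)
}

new_hairpin_structure <- function(seq, pairs, mfe, model) {
  structure(
    list(sequence = seq,
         dotbracket = dotbracket_from_pairs(nchar(seq), pairs),
         pairs = pairs,
         mfe = mfe,
         model = model),
    class = "hairpin_structure"
  )
}

#' Stability filter for folded hairpins
#'
#' A candidate stem-loop passes the stability filter when its minimum free
#' energy is at or below the threshold (default -15 model units). The
#' comparison is inclusive: a structure exactly at the threshold passes.
#'
#' @param struct A `hairpin_structure` (or anything with an `mfe` field).
#' @param threshold Energy threshold in model units.
#' @return Logical flag.
#' @export
is_stable <- function(struct, threshold = -15) {
  mfe <- if (is.list(struct)) struct$mfe else struct
  stopifnot(is.numeric(mfe), length(mfe) == 1)
  mfe <= threshold
}

#' Score a given single-hairpin structure under an energy model
#'
#' Computes the energy of an explicit chain of nested pairs with the same
#' terms the folding engine uses. This is the single source of truth for the
#' energy of a structure and is also used by the test suite's enumeration
#' oracle, which searches structures independently of the dynamic program.
#'
#' @param seq RNA sequence.
#' @param pairs Two-column matrix of 1-based pair positions (i < j), in any
#'   order; must form a chain of nested pairs.
#' @param model An `energy_model`.
#' @return The structure's energy (model units); `Inf` if the structure is
#'   not a legal single hairpin under the model (non-chain, illegal pair,
#'   loop below the minimum, or interior loop beyond `max_interior`).
#' @export
structure_energy <- function(seq, pairs, model = default_energy_model()) {
  seq <- as_rna(seq, allow_n = FALSE)
  s <- seq_chars(seq)
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  i <- pairs[, 1]; j <- pairs[, 2]
  if (any(i >= j)) return(Inf)
  # chain of nested pairs: i strictly increasing, j strictly decreasing
  if (nrow(pairs) > 1 &&
      (any(diff(i) <= 0) || any(diff(j) >= 0))) return(Inf)
  pn <- pair_name_of(s[i], s[j])
  if (anyNA(pn)) return(Inf)
  inner <- nrow(pairs)
  loop <- j[inner] - i[inner] - 1
  if (loop < model$min_loop) return(Inf)
  e <- hairpin_penalty(model, loop) + end_penalty(model, pn[1])
  if (nrow(pairs) > 1) {
    for (k in seq_len(nrow(pairs) - 1)) {
      l1 <- i[k + 1] - i[k] - 1
      l2 <- j[k] - j[k + 1] - 1
      if (l1 > model$max_interior || l2 > model$max_interior) return(Inf)
      e <- e + if (l1 == 0 && l2 == 0) {
        model$stacks[pn[k], pn[k + 1]]
      } else if (l1 == 0 || l2 == 0) {
        bulge_penalty(model, l1 + l2)
      } else {
        internal_penalty(model, l1, l2)
      }
    }
  }
  unname(e)
}

# Dot-bracket helpers --------------------------------------------------------

dotbracket_from_pairs <- function(n, pairs) {
  d <- rep(".", n)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    d[pairs[, 1]] <- "("
    d[pairs[, 2]] <- ")"
  }
  paste(d, collapse = "")
}

#' Convert a dot-bracket string to a pair matrix
#'
#' @param db Dot-bracket string.
#' @return Two-column integer matrix of 1-based `(i, j)` pairs, `i < j`.
#' @export
pairs_from_dotbracket <- function(db) {
  d <- seq_chars(db)
  stack <- integer(0)
  out <- matrix(integer(0), 0, 2)
  for (k in seq_along(d)) {
    if (d[k] == "(") {
      stack <- c(stack, k)
    } else if (d[k] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      out <- rbind(out, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  out[order(out[, 1]), , drop = FALSE]
}

# Loop span (first and last unpaired position of the terminal loop), or NULL
# for an unpaired structure.
loop_span <- function(hp) {
  if (nrow(hp$pairs) == 0) return(NULL)
  inner <- hp$pairs[nrow(hp$pairs), ]
  c(inner[1] + 1L, inner[2] - 1L)
}

# Partner lookup table: partner[i] = j if paired, 0 otherwise.
partner_table <- function(hp) {
  p <- integer(nchar(hp$sequence))
  if (nrow(hp$pairs) > 0) {
    p[hp$pairs[, 1]] <- hp$pairs[, 2]
    p[hp$pairs[, 2]] <- hp$pairs[, 1]
  }
  p
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat("<hairpin_structure> ", nchar(x$sequence), " nt, ",
      nrow(x$pairs), " pairs, MFE = ", format(x$mfe, digits = 4),
      " model units\n", sep = "")
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Tidy a folded hairpin into a per-pair tibble
#'
#' @param x A `hairpin_structure`.
#' @param ... Unused.
#' @return A tibble with one row per base pair (outermost first): positions,
#'   bases and pair type.
#' @export
tidy.hairpin_structure <- function(x, ...) {
  s <- seq_chars(x$sequence)
  if (nrow(x$pairs) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          base_i = character(), base_j = character(),
                          pair = character()))
  }
  tibble::tibble(
    i = x$pairs[, 1], j = x$pairs[, 2],
    base_i = s[x$pairs[, 1]], base_j = s[x$pairs[, 2]],
    pair = paste0(s[x$pairs[, 1]], s[x$pairs[, 2]])
  )
}

#' One-row summary of a folded hairpin
#'
#' @param x A `hairpin_structure`.
#' @param ... Unused.
#' @return A tibble with length, pair count, loop size, MFE and stability at
#'   the default -15 threshold.
#' @export
glance.hairpin_structure <- function(x, ...) {
  ls <- loop_span(x)
  tibble::tibble(
    length = nchar(x$sequence),
    n_pairs = nrow(x$pairs),
    loop_size = if (is.null(ls)) NA_integer_ else ls[2] - ls[1] + 1L,
    mfe = x$mfe,
    stable = is_stable(x)
  )
}

#' Write structures in Vienna-style plain text
#'
#' Emits, per record: a `>` header line, the sequence line, and the
#' dot-bracket line with the energy in parentheses.
#'
#' @param structs A `hairpin_structure` or list of them.
#' @param path Output file.
#' @param ids Record identifiers.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(structs, path, ids = NULL) {
  if (inherits(structs, "hairpin_structure")) structs <- list(structs)
  if (is.null(ids)) ids <- paste0("structure_", seq_along(structs))
  lines <- unlist(purrr::map2(structs, ids, function(h, id) {
    c(paste0(">", id), h$sequence,
      sprintf("%s (%.2f)", h$dotbracket, h$mfe))
  }))
  writeLines(lines, path)
  invisible(path)
}
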