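#' Extract loops from a secondary structure
#'
#' Enumerates the faces of the nested pairing layer and classifies each as a
#' hairpin (one closing pair), bulge (two closing pairs, one empty side),
#' internal loop (two closing pairs, two non-empty sides) or multibranch loop
#' (three or more closing pairs). Following the usual motif-extraction rule,
#' a loop is kept only when every bounding helix carries at least two
#' consecutive stacked pairs (the closing pair plus one flanking pair) and
#' none of its unpaired residues participates in a pseudoknot pair. The
#' exterior face is never reported.
#'
#' @param s An [rna_structure].
#' @param keep_dropped Keep ineligible loops (thin helices, pseudoknot
#'   involvement) in the output, flagged by `eligible`/`pk_involved`.
#' @return A tibble with one row per loop: `loop_id`, `loop_type`, `motif`,
#'   `n_unpaired`, and list-columns `sides` (runs of unpaired positions, 5'
#'   side first), `positions` (all unpaired positions), `closing_pairs` and
#'   `flanking_pairs` (two-column matrices, outermost helix first).
#' @export
#' @examples
#' s <- parse_dotbracket("(((.((....)).)))", "GGGAGGAAAACCACCC")
#' extract_loops(s)
extract_loops <- function(s, keep_dropped = FALSE) {
  L <- rna_length(s)
  pn <- partner_vector(s, nested_only = TRUE)
  pkpos <- pk_positions(s)
  nested <- s$pairs[!s$pairs$pk, , drop = FALSE]
  in_nested <- function(i, j) {
    i >= 1L && j <= L && pn[i] == j
  }

  rows <- list()
  if (nrow(nested) > 0L) {
    for (r in seq_len(nrow(nested))) {
      i <- nested$i[r]; j <- nested$j[r]
      # walk the face closed by (i, j)
      runs <- list()
      children <- list()
      cur <- integer()
      k <- i + 1L
      while (k < j) {
        if (pn[k] == 0L || pn[k] < k) {
          # pn[k] < k cannot happen inside a nested face, defensive only
          cur <- c(cur, k)
          k <- k + 1L
        } else {
          runs[[length(runs) + 1L]] <- cur
          cur <- integer()
          children[[length(children) + 1L]] <- c(k, pn[k])
          k <- pn[k] + 1L
        }
      }
      runs[[length(runs) + 1L]] <- cur
      nc <- length(children)
      if (nc == 1L && length(runs[[1]]) == 0L && length(runs[[2]]) == 0L) {
        next # stacked helix, not a loop
      }
      loop_type <- if (nc == 0L) "hairpin"
        else if (nc == 1L) {
          if (length(runs[[1]]) == 0L || length(runs[[2]]) == 0L) "bulge"
          else "internal"
        } else "multibranch"

      closing <- rbind(c(i, j), do.call(rbind, children))
      # flanking pair of the outer helix sits outside (i-1, j+1); for each
      # child helix it sits inside (k+1, l-1)
      flank <- matrix(NA_integer_, nrow = nrow(closing), ncol = 2)
      ok <- TRUE
      if (in_nested(i - 1L, j + 1L)) flank[1, ] <- c(i - 1L, j + 1L) else ok <- FALSE
      if (nc > 0L) {
        for (c0 in seq_len(nc)) {
          kk <- children[[c0]][1]; ll <- children[[c0]][2]
          if (kk + 1L < ll && in_nested(kk + 1L, ll - 1L)) {
            flank[c0 + 1L, ] <- c(kk + 1L, ll - 1L)
          } else ok <- FALSE
        }
      }
      positions <- sort(unlist(runs))
      pk_involved <- length(pkpos) > 0L && any(positions %in% pkpos)
      sides <- if (loop_type == "bulge") {
        runs[lengths(runs) > 0L]
      } else if (loop_type == "hairpin") {
        runs[1]
      } else runs
      rows[[length(rows) + 1L]] <- list(
        loop_type = loop_type,
        sides = sides,
        positions = positions,
        closing_pairs = closing,
        flanking_pairs = flank,
        eligible = ok,
        pk_involved = pk_involved
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      loop_id = integer(), loop_type = character(), motif = character(),
      n_unpaired = integer(), sides = list(), positions = list(),
      closing_pairs = list(), flanking_pairs = list(),
      eligible = logical(), pk_involved = logical()
    ))
  }
  out <- tibble::tibble(
    loop_type = purrr::map_chr(rows, "loop_type"),
    sides = purrr::map(rows, "sides"),
    positions = purrr::map(rows, "positions"),
    closing_pairs = purrr::map(rows, "closing_pairs"),
    flanking_pairs = purrr::map(rows, "flanking_pairs"),
    eligible = purrr::map_lgl(rows, "eligible"),
    pk_involved = purrr::map_lgl(rows, "pk_involved")
  )
  out <- dplyr::mutate(
    out,
    motif = purrr::map2_chr(.data$loop_type, .data$sides, motif_string),
    n_unpaired = lengths(.data$positions)
  )
  out <- dplyr::arrange(out, purrr::map_int(.data$closing_pairs, ~ .x[1, 1]))
  out <- dplyr::mutate(out, loop_id = dplyr::row_number())
  out <- dplyr::select(out, "loop_id", "loop_type", "motif", "n_unpaired",
                       "sides", "positions", "closing_pairs", "flanking_pairs",
                       "eligible", "pk_involved")
  if (!keep_dropped) {
    out <- dplyr::filter(out, .data$eligible, !.data$pk_involved)
    out <- dplyr::select(out, -"eligible", -"pk_involved")
  }
  out
}

# motif label: hairpin-4, bulge-2, internal-1x2 (shorter side first),
# multibranch-<sorted run lengths>
motif_string <- function(loop_type, sides) {
  len <- lengths(sides)
  switch(loop_type,
    hairpin = paste0("hairpin-", len[1]),
    bulge = paste0("bulge-", len[1]),
    internal = paste0("internal-", min(len), "x", max(len)),
    multibranch = paste0("multibranch-", paste(sort(len), collapse = "_"))
  )
}

#' Motif signature of a loop
#'
#' Hairpin and bulge motifs are labelled by their single run length
#' (`hairpin-4`, `bulge-2`); internal loops are canonicalized to
#' `internal-<min>x<max>` so that 1x2 and 2x1 loops share a motif. The
#' canonicalization is idempotent.
#'
#' @param loops A loop tibble from [extract_loops()], or one row of it.
#' @return Character vector of motif labels.
#' @export
motif_of <- function(loops) {
  purrr::map2_chr(loops$loop_type, loops$sides, motif_string)
}

#' Sequence positions of a loop in motif enumeration order
#'
#' Positions are counted from the 5' end of the loop motif. For internal
#' loops the shorter side is enumerated first; when the 5' side is the
#' longer one, the loop is read mirrored (both sides reversed, 3' side
#' first), so that asymmetric loops map onto their canonical motif.
#'
#' @param loop_type Loop type string.
#' @param sides List of integer vectors of unpaired positions (5' side first).
#' @return Integer vector: the sequence position of motif positions `1..k`.
#' @export
motif_positions <- function(loop_type, sides) {
  if (loop_type %in% c("hairpin", "bulge")) {
    return(sides[[1]])
  }
  if (loop_type == "internal") {
    a <- sides[[1]]; b <- sides[[2]]
    if (length(a) <= length(b)) c(a, b) else c(rev(b), rev(a))
  } else {
    sort(unlist(sides))
  }
}

# stable identity key used for "the same loop" across structures
loop_key <- function(loop_type, positions, closing_pairs) {
  paste0(loop_type, "|", paste(positions, collapse = ","), "|",
         paste(t(closing_pairs), collapse = ","))
}

loop_keys <- function(loops) {
  purrr::pmap_chr(
    list(loops$loop_type, loops$positions, loops$closing_pairs),
    loop_key
  )
}
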