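#' Create an RNA secondary structure object
#'
#' An `rna_structure` bundles a nucleotide sequence with a base-pair table.
#' Pairs are 1-based `(i, j)` with `i < j`; each position may participate in
#' at most one pair. The pair set is split into a properly nested layer and a
#' pseudoknot layer (`pk`): pairs crossing the nested layer. When `pk` is not
#' supplied, pairs are assigned greedily to non-crossing layers in 5' order;
#' the first layer is the nested one and everything else is flagged `pk`.
#'
#' @param sequence Single string over `A`, `C`, `G`, `U`, `N` (case kept as
#'   given; `T` is accepted and treated as `U` for pairing checks).
#' @param pairs A two-column matrix or data frame of paired positions, or
#'   `NULL` for an unpaired structure.
#' @param pk Optional logical vector, one entry per pair row, flagging
#'   pseudoknotted pairs. If `NULL` the layering is inferred.
#' @param warn_noncanonical Warn when a pair is not A-U, G-C or G-U. Ensembles
#'   from motif-based folding engines legitimately contain such pairs, so they
#'   are accepted.
#' @return An object of class `rna_structure` with elements `sequence` and
#'   `pairs` (a tibble with columns `i`, `j`, `pk`, sorted by `i`).
#' @export
#' @examples
#' s <- rna_structure("GGGGAAAACCCC", cbind(1:4, 12:9))
#' s
rna_structure <- function(sequence, pairs = NULL, pk = NULL,
                          warn_noncanonical = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  bad <- stringr::str_detect(toupper(sequence), "[^ACGUNT]")
  if (bad) stop("sequence contains characters outside {A,C,G,U,N,T}")

  if (is.null(pairs) || NROW(pairs) == 0L) {
    tbl <- tibble::tibble(i = integer(), j = integer(), pk = logical())
    return(new_rna_structure(sequence, tbl))
  }
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  dimnames(pairs) <- NULL
  storage.mode(pairs) <- "integer"
  swap <- pairs[, 1] > pairs[, 2]
  pairs[swap, ] <- pairs[swap, 2:1]
  if (any(pairs[, 1] == pairs[, 2])) stop("a position cannot pair with itself")
  if (any(pairs < 1L) || any(pairs > L)) {
    stop("pair index out of range [1, ", L, "]")
  }
  idx <- c(pairs[, 1], pairs[, 2])
  if (anyDuplicated(idx)) {
    stop("position(s) ", paste(unique(idx[duplicated(idx)]), collapse = ", "),
         " appear in more than one pair")
  }
  ord <- order(pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  if (is.null(pk)) {
    pk <- assign_pk_layers(pairs)
  } else {
    stopifnot(is.logical(pk), length(pk) == NROW(pairs) || length(pk) == length(ord))
    pk <- pk[ord]
    nested <- pairs[!pk, , drop = FALSE]
    if (any_crossing(nested)) {
      stop("non-pseudoknot pairs are not properly nested")
    }
  }
  if (warn_noncanonical) {
    sq <- chartr("T", "U", toupper(sequence))
    b1 <- substring(sq, pairs[, 1], pairs[, 1])
    b2 <- substring(sq, pairs[, 2], pairs[, 2])
    duo <- paste0(pmin(b1, b2), pmax(b1, b2))
    ok <- duo %in% c("AU", "CG", "GU") | b1 == "N" | b2 == "N"
    if (any(!ok)) {
      warning(sum(!ok), " non-canonical pair(s) (not A-U/G-C/G-U) accepted")
    }
  }
  new_rna_structure(sequence,
                    tibble::tibble(i = pairs[, 1], j = pairs[, 2], pk = pk))
}

new_rna_structure <- function(sequence, pairs) {
  structure(list(sequence = sequence, pairs = pairs), class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", nchar(x$sequence), " nt, ",
      nrow(x$pairs), " pairs (", sum(x$pairs$pk), " pseudoknotted)\n", sep = "")
  cat(x$sequence, "\n")
  cat(write_dotbracket(x), "\n")
  invisible(x)
}

rna_length <- function(s) nchar(s$sequence)

# partner vector over all pairs (0 = unpaired)
partner_vector <- function(s, nested_only = FALSE) {
  p <- integer(rna_length(s))
  tbl <- s$pairs
  if (nested_only) tbl <- tbl[!tbl$pk, , drop = FALSE]
  p[tbl$i] <- tbl$j
  p[tbl$j] <- tbl$i
  p
}

pk_positions <- function(s) {
  tbl <- s$pairs[s$pairs$pk, , drop = FALSE]
  sort(c(tbl$i, tbl$j))
}

# TRUE when any two pairs (i,j), (k,l) interleave as i < k < j < l
any_crossing <- function(mat) {
  n <- NROW(mat)
  if (n < 2L) return(FALSE)
  i <- mat[, 1]; j <- mat[, 2]
  for (a in seq_len(n - 1L)) {
    b <- (a + 1L):n
    if (any(i[b] < j[a] & j[b] > j[a] & i[b] > i[a])) return(TRUE)
  }
  FALSE
}

# greedy layering: each pair goes to the first layer it does not cross;
# layer 1 is the nested layer, the rest are pseudoknots
assign_pk_layers <- function(pairs) {
  n <- NROW(pairs)
  layer <- integer(n)
  layers <- list()
  for (a in seq_len(n)) {
    placed <- FALSE
    for (l in seq_along(layers)) {
      members <- layers[[l]]
      im <- pairs[members, 1]; jm <- pairs[members, 2]
      cross <- any((im < pairs[a, 1] & pairs[a, 1] < jm & jm < pairs[a, 2]) |
                   (pairs[a, 1] < im & im < pairs[a, 2] & pairs[a, 2] < jm))
      if (!cross) {
        layers[[l]] <- c(members, a)
        layer[a] <- l
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      layers[[length(layers) + 1L]] <- a
      layer[a] <- length(layers)
    }
  }
  layer > 1L
}

#' Test two structures for identity
#'
#' Same sequence (case-insensitive) and identical base-pair sets.
#'
#' @param a,b [rna_structure] objects.
#' @return Logical scalar.
#' @export
structure_equal <- function(a, b) {
  identical(toupper(a$sequence), toupper(b$sequence)) &&
    nrow(a$pairs) == nrow(b$pairs) &&
    all(a$pairs$i == b$pairs$i) && all(a$pairs$j == b$pairs$j)
}

pair_key <- function(s) paste(s$pairs$i, s$pairs$j, sep = ":", collapse = ";")

#' Parse a dot-bracket string into an [rna_structure]
#'
#' The round-bracket layer `()` forms the nested layer; `[]`, `{}` and `<>`
#' layers are treated as pseudoknots.
#'
#' @param text Dot-bracket string, same length as `sequence`.
#' @param sequence Nucleotide sequence.
#' @inheritParams rna_structure
#' @return An [rna_structure].
#' @export
#' @examples
#' parse_dotbracket("((((....))))", "GGGGAAAACCCC")
parse_dotbracket <- function(text, sequence, warn_noncanonical = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) != nchar(sequence)) {
    stop("structure length (", nchar(text), ") != sequence length (",
         nchar(sequence), ")")
  }
  opens <- c("(", "[", "{", "<")
  closes <- c(")", "]", "}", ">")
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  stacks <- rep(list(integer()), 4L)
  out_i <- integer(); out_j <- integer(); out_pk <- logical()
  for (pos in seq_along(ch)) {
    c0 <- ch[pos]
    if (c0 == "." || c0 == "-") next
    lo <- match(c0, opens)
    if (!is.na(lo)) {
      stacks[[lo]] <- c(stacks[[lo]], pos)
      next
    }
    lc <- match(c0, closes)
    if (!is.na(lc)) {
      st <- stacks[[lc]]
      if (length(st) == 0L) {
        stop("unbalanced '", c0, "' at position ", pos)
      }
      out_i <- c(out_i, st[length(st)])
      out_j <- c(out_j, pos)
      out_pk <- c(out_pk, lc > 1L)
      stacks[[lc]] <- st[-length(st)]
      next
    }
    stop("unsupported character '", c0, "' at position ", pos)
  }
  for (l in 1:4) {
    if (length(stacks[[l]]) > 0L) {
      stop("unbalanced '", opens[l], "' at position ",
           stacks[[l]][length(stacks[[l]])])
    }
  }
  rna_structure(sequence, cbind(out_i, out_j), pk = out_pk,
                warn_noncanonical = warn_noncanonical)
}

#' Write an [rna_structure] as a dot-bracket string
#'
#' Nested pairs are written with `()`; pseudoknot pairs are layered greedily
#' into `[]`, `{}` and `<>`.
#'
#' @param s An [rna_structure].
#' @return A dot-bracket string.
#' @export
write_dotbracket <- function(s) {
  ch <- rep(".", rna_length(s))
  nested <- s$pairs[!s$pairs$pk, , drop = FALSE]
  ch[nested$i] <- "("
  ch[nested$j] <- ")"
  pkp <- s$pairs[s$pairs$pk, , drop = FALSE]
  if (nrow(pkp) > 0L) {
    mat <- cbind(pkp$i, pkp$j)
    sub_layer <- integer(nrow(mat))
    layers <- list()
    for (a in seq_len(nrow(mat))) {
      placed <- FALSE
      for (l in seq_along(layers)) {
        m <- layers[[l]]
        im <- mat[m, 1]; jm <- mat[m, 2]
        cross <- any((im < mat[a, 1] & mat[a, 1] < jm & jm < mat[a, 2]) |
                     (mat[a, 1] < im & im < mat[a, 2] & mat[a, 2] < jm))
        if (!cross) {
          layers[[l]] <- c(m, a); sub_layer[a] <- l; placed <- TRUE; break
        }
      }
      if (!placed) {
        layers[[length(layers) + 1L]] <- a
        sub_layer[a] <- length(layers)
      }
    }
    if (length(layers) > 3L) {
      stop("more than three pseudoknot layers cannot be written in bracket form")
    }
    op <- c("[", "{", "<"); cl <- c("]", "}", ">")
    for (a in seq_len(nrow(mat))) {
      ch[mat[a, 1]] <- op[sub_layer[a]]
      ch[mat[a, 2]] <- cl[sub_layer[a]]
    }
  }
  paste(ch, collapse = "")
}

#' Parse CT-format text into an [rna_structure]
#'
#' Standard 6-column CT records: position, base, previous, next, pairing
#' partner (0 for unpaired), natural numbering. The first line is a header
#' (`count [title]`).
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @inheritParams rna_structure
#' @return An [rna_structure].
#' @export
parse_ct <- function(text, warn_noncanonical = FALSE) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty CT input")
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head_tok[1]))
  if (is.na(n)) stop("line 1: CT header must start with the residue count")
  body <- lines[-1]
  if (length(body) < n) stop("CT body has ", length(body), " rows, header says ", n)
  base <- character(n)
  pair_of <- integer(n)
  seen <- logical(n)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(tok) < 6L) stop("line ", k + 1L, ": expected 6 CT columns")
    idx <- suppressWarnings(as.integer(tok[1]))
    pj <- suppressWarnings(as.integer(tok[5]))
    if (is.na(idx) || is.na(pj)) stop("line ", k + 1L, ": non-numeric CT field")
    if (idx < 1L || idx > n) stop("line ", k + 1L, ": index ", idx, " out of range")
    if (seen[idx]) stop("line ", k + 1L, ": duplicate index ", idx)
    seen[idx] <- TRUE
    if (pj < 0L || pj > n) stop("line ", k + 1L, ": partner ", pj, " out of range")
    base[idx] <- tok[2]
    pair_of[idx] <- pj
  }
  # symmetry check
  for (idx in which(pair_of > 0L)) {
    if (pair_of[pair_of[idx]] != idx) {
      stop("inconsistent CT pairing: ", idx, " -> ", pair_of[idx],
           " but ", pair_of[idx], " -> ", pair_of[pair_of[idx]])
    }
  }
  ii <- which(pair_of > 0L & seq_len(n) < pair_of)
  pairs <- if (length(ii)) cbind(ii, pair_of[ii]) else NULL
  rna_structure(paste(base, collapse = ""), pairs,
                warn_noncanonical = warn_noncanonical)
}

#' Write an [rna_structure] as CT-format lines
#'
#' @param s An [rna_structure].
#' @param title Header title string.
#' @return Character vector of CT lines.
#' @export
write_ct <- function(s, title = "") {
  L <- rna_length(s)
  p <- partner_vector(s)
  base <- strsplit(s$sequence, "", fixed = TRUE)[[1]]
  c(paste(L, title),
    sprintf("%d %s %d %d %d %d",
            seq_len(L), base, seq_len(L) - 1L,
            ifelse(seq_len(L) == L, 0L, seq_len(L) + 1L), p, seq_len(L)))
}

#' Read / write multi-structure dot-bracket files
#'
#' Files hold one or more records: a `>name` header, an optional sequence
#' line (required for the first record, reused afterwards when omitted), and
#' a structure line.
#'
#' @param path File path.
#' @return `read_structures()`: a named list of [rna_structure] objects.
#' @export
read_structures <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  cur_name <- NULL
  cur_seq <- NULL
  last_seq <- NULL
  pending <- character()
  flush <- function() {
    if (is.null(cur_name)) return()
    if (length(pending) == 0L) stop("record '", cur_name, "' has no structure line")
    sq <- cur_seq %||% last_seq
    if (is.null(sq)) stop("record '", cur_name, "' has no sequence")
    out[[cur_name]] <<- parse_dotbracket(pending[1], sq)
    last_seq <<- sq
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- sub("^>\\s*", "", ln)
      if (!nzchar(cur_name)) cur_name <- paste0("structure_", length(out) + 1L)
      cur_seq <- NULL
      pending <- character()
    } else if (grepl("^[ACGUNTacgunt]+$", ln)) {
      cur_seq <- ln
    } else {
      pending <- c(pending, ln)
    }
  }
  flush()
  out
}

#' @rdname read_structures
#' @param structures Named list of [rna_structure] objects.
#' @export
write_structures <- function(structures, path) {
  if (is.null(names(structures))) {
    names(structures) <- paste0("structure_", seq_along(structures))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(structures)) {
    s <- structures[[nm]]
    writeLines(c(paste0(">", nm), s$sequence, write_dotbracket(s)), con)
  }
  invisible(path)
}

#' Parse a SHAPE reactivity profile
#'
#' Two whitespace-separated columns: 1-based position and reactivity; the
#' value `-999` (the conventional SHAPE sentinel) and absent positions are
#' recorded as missing (`NA`).
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @param length Profile length; defaults to the largest index present.
#' @return A `shape_profile`: a numeric vector with `NA` for missing values.
#' @export
#' @examples
#' parse_shape(c("1 0.8", "2 -999", "3 0.1"))
parse_shape <- function(text, length = NULL) {
  lines <- if (base::length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  lines <- lines[nzchar(trimws(lines))]
  idx <- integer(0)
  val <- numeric(0)
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (base::length(tok) < 2L) stop("line ", k, ": expected two columns")
    i <- suppressWarnings(as.integer(tok[1]))
    v <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(i)) stop("line ", k, ": non-numeric index '", tok[1], "'")
    if (is.na(v)) stop("line ", k, ": non-numeric reactivity '", tok[2], "'")
    if (i < 1L) stop("line ", k, ": index ", i, " out of range")
    if (i %in% idx) stop("line ", k, ": duplicate index ", i)
    idx <- c(idx, i)
    val <- c(val, v)
  }
  L <- length %||% (if (base::length(idx)) max(idx) else 0L)
  if (base::length(idx) && max(idx) > L) {
    stop("index ", max(idx), " exceeds profile length ", L)
  }
  x <- rep(NA_real_, L)
  x[idx] <- val
  x[!is.na(x) & x <= -998] <- NA_real_
  shape_profile(x)
}

#' Construct a SHAPE profile from a numeric vector
#'
#' @param x Numeric vector of reactivities; `NA` marks missing data.
#' @return A `shape_profile`.
#' @export
shape_profile <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x) & !is.na(x))) stop("non-finite reactivity value")
  structure(x, class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat("<shape_profile> ", length(x), " positions, ",
      sum(is.na(x)), " missing\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname parse_shape
#' @param profile A `shape_profile`.
#' @param path File path.
#' @export
write_shape <- function(profile, path) {
  v <- ifelse(is.na(profile), -999, as.numeric(profile))
  writeLines(sprintf("%d\t%.6g", seq_along(v), v), path)
  invisible(path)
}

#' @rdname read_structures
#' @export
read_ct <- function(path) parse_ct(readLines(path, warn = FALSE))

#' @rdname parse_shape
#' @export
read_shape <- function(path, length = NULL) {
  parse_shape(readLines(path, warn = FALSE), length = length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
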