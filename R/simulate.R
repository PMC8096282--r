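#' Specification for synthetic RNA benchmarks
#'
#' Describes the statistical structure the generator emulates: paired
#' residues draw low reactivities, loop residues draw higher ones, and
#' selected loop-motif positions carry planted mean offsets — the same
#' position-wise signal the pattern-discovery stage is designed to detect.
#'
#' @param rna_length Target sequence length; the assembled units are padded
#'   with exterior residues up to this length (error when they do not fit).
#' @param motifs Named integer vector of requested loop motifs, e.g.
#'   `c("hairpin-4" = 2, "internal-1x2" = 1, "bulge-2" = 1)`.
#' @param paired_mean,paired_sd Reactivity distribution of paired residues
#'   (normal truncated at 0; defaults 0.1, 0.1).
#' @param loop_mean,loop_sd Base reactivity distribution of unpaired
#'   residues (truncated normal; defaults 0.5, 0.25).
#' @param planted Tibble (`motif`, `position`, `offset`) of mean-reactivity
#'   offsets added at specific motif positions of every loop of that motif,
#'   or `NULL` for none. [default_planted_patterns()] supplies offsets of
#'   +0.4 at one position of each common motif.
#' @param missing_rate Probability that a position is reported missing.
#' @param helix_length Stacked pairs per generated helix (>= 2 so that every
#'   loop satisfies the two-flanking-pair rule; default 3).
#' @param terminal_hairpin Loop length of the hairpin that caps bulge and
#'   internal units when no requested hairpin motif is available (default 4).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(rna_length = 200L,
                       motifs = c("hairpin-4" = 1L),
                       paired_mean = 0.1, paired_sd = 0.1,
                       loop_mean = 0.5, loop_sd = 0.25,
                       planted = default_planted_patterns(),
                       missing_rate = 0.05,
                       helix_length = 3L,
                       terminal_hairpin = 4L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1, helix_length >= 2L,
            paired_sd > 0, loop_sd > 0)
  if (!is.null(planted)) {
    stopifnot(all(c("motif", "position", "offset") %in% names(planted)),
              all(is.finite(planted$offset)))
  }
  structure(list(rna_length = as.integer(rna_length), motifs = motifs,
                 paired_mean = paired_mean, paired_sd = paired_sd,
                 loop_mean = loop_mean, loop_sd = loop_sd,
                 planted = planted, missing_rate = missing_rate,
                 helix_length = as.integer(helix_length),
                 terminal_hairpin = as.integer(terminal_hairpin)),
            class = "synth_spec")
}

#' Default planted reactivity offsets
#'
#' One elevated (+`offset`) and one depressed (`low_offset`) position per
#' common motif, mimicking the position-wise reactivity preferences of real
#' loop motifs — tetraloops, for instance, are reactive at their central
#' residues and unreactive at the first.
#'
#' @param offset Mean reactivity offset of the elevated position
#'   (default 0.8: a reactive apex near 1.3 on the normalized SHAPE scale).
#' @param low_offset Offset of the depressed position (default -0.35: an
#'   unreactive loop residue comparable to a paired one).
#' @return A tibble (`motif`, `position`, `offset`).
#' @export
default_planted_patterns <- function(offset = 0.8, low_offset = -0.35) {
  dplyr::bind_rows(
    tibble::tibble(
      motif = c("hairpin-4", "hairpin-6", "bulge-2", "internal-1x2",
                "internal-2x2"),
      position = c(2L, 5L, 1L, 1L, 2L),
      offset = offset
    ),
    # two unreactive positions per motif (like the first and last residues
    # of UNCG/GNRA tetraloops), so both top-ranked patterns are strong
    tibble::tibble(
      motif = c("hairpin-4", "hairpin-4", "hairpin-6", "hairpin-6",
                "bulge-2", "internal-1x2", "internal-1x2",
                "internal-2x2", "internal-2x2"),
      position = c(1L, 4L, 1L, 2L, 2L, 2L, 3L, 1L, 4L),
      offset = low_offset
    )
  )
}

# dot-bracket fragments for one structural unit; consumes hairpin requests
# as terminal hairpins of bulge/internal units when available
unit_db <- function(kind, a, b, h, hp) {
  hx <- function(n, ch) strrep(ch, n)
  switch(kind,
    hairpin = paste0(hx(h, "("), strrep(".", a), hx(h, ")")),
    bulge = paste0(hx(h, "("), strrep(".", a),
                   hx(h, "("), strrep(".", hp), hx(h, ")"), hx(h, ")")),
    internal = paste0(hx(h, "("), strrep(".", a),
                      hx(h, "("), strrep(".", hp), hx(h, ")"),
                      strrep(".", b), hx(h, ")")),
    multibranch = paste0(hx(h, "("), ".",
                         hx(h, "("), strrep(".", hp), hx(h, ")"), ".",
                         hx(h, "("), strrep(".", hp), hx(h, ")"), ".",
                         hx(h, ")"))
  )
}

parse_motif <- function(m) {
  if (grepl("^hairpin-[0-9]+$", m)) {
    list(kind = "hairpin", a = as.integer(sub("hairpin-", "", m)), b = 0L)
  } else if (grepl("^bulge-[0-9]+$", m)) {
    list(kind = "bulge", a = as.integer(sub("bulge-", "", m)), b = 0L)
  } else if (grepl("^internal-[0-9]+x[0-9]+$", m)) {
    ab <- as.integer(strsplit(sub("internal-", "", m), "x")[[1]])
    list(kind = "internal", a = ab[1], b = ab[2])
  } else if (grepl("^multibranch", m)) {
    list(kind = "multibranch", a = 0L, b = 0L)
  } else stop("unknown motif '", m, "'")
}

#' Generate a nested structure containing requested loop motifs
#'
#' Builds one stem-loop unit per requested motif (helices of
#' `helix_length` stacked pairs, so every loop carries two flanking pairs),
#' shuffles the unit order, joins them with exterior spacers and pads to
#' `rna_length`. Requested hairpin motifs are used as the terminal hairpins
#' of bulge/internal units where possible, so the extracted motif inventory
#' matches the request. Paired positions receive complementary bases
#' (including occasional G-U wobbles); generation is deterministic per
#' seed.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return An [rna_structure].
#' @export
generate_structure <- function(spec, seed = 1L) {
  withr::with_seed(seed, generate_structure_impl(spec))
}

generate_structure_impl <- function(spec) {
  h <- spec$helix_length
  req <- spec$motifs
  req <- req[req > 0]
  motif_list <- rep(names(req), times = req)
  parsed <- purrr::map(motif_list, parse_motif)
  kinds <- purrr::map_chr(parsed, "kind")
  # hairpin requests available to cap bulge/internal/multibranch units
  hp_pool <- purrr::map_int(parsed[kinds == "hairpin"], "a")
  hp_standalone <- logical(length(hp_pool))
  units <- character(0)
  for (k in seq_along(parsed)) {
    p <- parsed[[k]]
    if (p$kind == "hairpin") next
    n_need <- if (p$kind == "multibranch") 2L else 1L
    caps <- integer(0)
    for (q in seq_len(n_need)) {
      free <- which(!hp_standalone)
      if (length(free) > 0L) {
        hp_standalone[free[1]] <- TRUE
        caps <- c(caps, hp_pool[free[1]])
      } else {
        caps <- c(caps, spec$terminal_hairpin)
      }
    }
    units <- c(units, if (p$kind == "multibranch") {
      paste0(strrep("(", h), ".",
             unit_db("hairpin", caps[1], 0L, h, 0L), ".",
             unit_db("hairpin", caps[2], 0L, h, 0L), ".",
             strrep(")", h))
    } else {
      unit_db(p$kind, p$a, p$b, h, caps[1])
    })
  }
  # remaining hairpin requests become standalone units
  for (q in which(!hp_standalone)) {
    units <- c(units, unit_db("hairpin", hp_pool[q], 0L, h, 0L))
  }
  if (length(units) == 0L) stop("empty motif inventory")
  units <- sample(units)
  spacers <- strrep(".", sample(4:7, length(units) + 1L, replace = TRUE))
  db <- paste0(spacers[1],
               paste0(units, spacers[-1], collapse = ""))
  if (nchar(db) > spec$rna_length) {
    stop("motif inventory needs ", nchar(db),
         " nt but rna_length is ", spec$rna_length)
  }
  db <- paste0(db, strrep(".", spec$rna_length - nchar(db)))
  seq <- random_sequence_for(db)
  parse_dotbracket(db, seq)
}

# complementary sequence for a dot-bracket scaffold (92% Watson-Crick,
# 8% G-U wobble), random bases elsewhere
random_sequence_for <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  L <- length(ch)
  base <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  stack <- integer(0)
  for (pos in seq_len(L)) {
    if (ch[pos] == "(") stack <- c(stack, pos)
    else if (ch[pos] == ")") {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      duo <- sample(c("AU", "UA", "GC", "CG", "GU", "UG"), 1,
                    prob = c(0.23, 0.23, 0.23, 0.23, 0.04, 0.04))
      base[i] <- substr(duo, 1, 1)
      base[pos] <- substr(duo, 2, 2)
    }
  }
  paste(base, collapse = "")
}

rtruncnorm0 <- function(n, mean, sd) {
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a SHAPE profile for a structure
#'
#' Paired positions draw from the low paired-reactivity distribution;
#' unpaired positions from the loop base distribution; positions named in
#' the spec's planted pattern list additionally receive their mean offset
#' (mapped through the motif enumeration of each extracted loop, so
#' asymmetric internal loops are planted on their canonical positions).
#' Missing values are injected at `missing_rate`. Deterministic per seed.
#'
#' @param structure An [rna_structure].
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return A `shape_profile`.
#' @export
generate_shape <- function(structure, spec, seed = 1L) {
  withr::with_seed(seed, {
    L <- rna_length(structure)
    p <- partner_vector(structure)
    x <- numeric(L)
    paired <- p > 0L
    x[paired] <- rtruncnorm0(sum(paired), spec$paired_mean, spec$paired_sd)
    x[!paired] <- rtruncnorm0(sum(!paired), spec$loop_mean, spec$loop_sd)
    if (!is.null(spec$planted) && nrow(spec$planted) > 0L) {
      loops <- extract_loops(structure)
      for (k in seq_len(nrow(loops))) {
        pl <- spec$planted[spec$planted$motif == loops$motif[k], ,
                           drop = FALSE]
        if (nrow(pl) == 0L) next
        mp <- motif_positions(loops$loop_type[k], loops$sides[[k]])
        for (r in seq_len(nrow(pl))) {
          x[mp[pl$position[r]]] <- x[mp[pl$position[r]]] + pl$offset[r]
        }
      }
    }
    if (spec$missing_rate > 0) {
      x[stats::runif(L) < spec$missing_rate] <- NA_real_
    }
    shape_profile(x)
  })
}

#' Generate a candidate ensemble by local perturbation
#'
#' Each candidate is the true structure with some helices locally
#' re-drawn: with probability `perturb_rate` per helix, the helix is
#' shifted by 1-3 positions, shrunk or grown by 1-2 pairs, or deleted —
#' whichever keeps the pair set valid and nested. Stands in for a
#' Boltzmann-sampled suboptimal ensemble.
#'
#' @param true_structure The reference [rna_structure].
#' @param n Ensemble size.
#' @param perturb_rate Per-helix perturbation probability.
#' @param seed Integer seed.
#' @param include_true Force the true structure in (as the first
#'   candidate); when `FALSE` candidates equal to the truth are re-perturbed
#'   away.
#' @return List of [rna_structure] objects.
#' @export
generate_ensemble <- function(true_structure, n, perturb_rate = 0.3,
                              seed = 1L, include_true = TRUE) {
  stopifnot(n >= 1L)
  withr::with_seed(seed, {
    out <- vector("list", n)
    start <- 1L
    if (include_true) {
      out[[1]] <- true_structure
      start <- 2L
    }
    k <- start
    guard <- 0L
    while (k <= n) {
      cand <- perturb_structure(true_structure, perturb_rate,
                                force = !include_true)
      bad <- (!include_true && structure_equal(cand, true_structure)) ||
        # the fully open chain has negligible Boltzmann weight for a
        # structured RNA; never propose it
        (nrow(true_structure$pairs) > 0L && nrow(cand$pairs) == 0L)
      if (bad) {
        guard <- guard + 1L
        if (guard > 200L) stop("could not produce a valid candidate")
        next
      }
      out[[k]] <- cand
      k <- k + 1L
    }
    out
  })
}

# maximal stacked runs of nested pairs
helix_runs <- function(s) {
  nested <- s$pairs[!s$pairs$pk, , drop = FALSE]
  if (nrow(nested) == 0L) return(list())
  nested <- nested[order(nested$i), , drop = FALSE]
  runs <- list()
  cur <- 1L
  for (r in seq_len(nrow(nested))[-1]) {
    if (nested$i[r] == nested$i[r - 1L] + 1L &&
        nested$j[r] == nested$j[r - 1L] - 1L) {
      cur <- c(cur, r)
    } else {
      runs[[length(runs) + 1L]] <- nested[cur, , drop = FALSE]
      cur <- r
    }
  }
  runs[[length(runs) + 1L]] <- nested[cur, , drop = FALSE]
  runs
}

perturb_structure <- function(s, rate, force = FALSE) {
  runs <- helix_runs(s)
  pk <- s$pairs[s$pairs$pk, , drop = FALSE]
  L <- rna_length(s)
  out_runs <- list()
  touched <- FALSE
  relocations <- 0L
  for (h in runs) {
    hit <- stats::runif(1) < rate
    if (!hit) { out_runs[[length(out_runs) + 1L]] <- h; next }
    touched <- TRUE
    # local slips dominate; wholesale loss of a stacked helix is the kind
    # of move a Boltzmann-weighted sampler rarely proposes
    op <- sample(c("shift", "shrink", "grow", "delete", "relocate"), 1,
                 prob = c(0.15, 0.25, 0.25, 0.05, 0.3))
    if (op == "relocate") relocations <- relocations + 1L
    nh <- switch(op,
      shift = {
        k <- sample(c(-5:-2, 2:5), 1)
        tibble::tibble(i = h$i + k, j = h$j + k, pk = h$pk)
      },
      shrink = {
        k <- min(sample(1:2, 1), nrow(h) - 2L)
        if (k < 1L) NULL else h[seq_len(nrow(h) - k), , drop = FALSE]
      },
      grow = {
        k <- sample(1:2, 1)
        add <- tibble::tibble(i = h$i[nrow(h)] + seq_len(k),
                              j = h$j[nrow(h)] - seq_len(k),
                              pk = FALSE)
        dplyr::bind_rows(h, add)
      },
      delete = NULL,
      relocate = NULL
    )
    if (!is.null(nh)) out_runs[[length(out_runs) + 1L]] <- nh
  }
  if (force && !touched && length(runs) > 0L) {
    # guarantee at least one change when the truth must be excluded
    pick <- sample(length(out_runs), 1)
    h <- out_runs[[pick]]
    out_runs[[pick]] <- if (nrow(h) > 1L) h[-nrow(h), , drop = FALSE] else NULL
    out_runs <- out_runs[!purrr::map_lgl(out_runs, is.null)]
  }
  tbl <- dplyr::bind_rows(out_runs)
  tbl <- dplyr::bind_rows(tbl, pk)
  if (nrow(tbl) == 0L) return(rna_structure(s$sequence, NULL))
  # validity: in range, i < j with a positive gap, no reuse, nested layer
  ok <- tbl$i >= 1L & tbl$j <= L & tbl$j - tbl$i >= 4L
  tbl <- tbl[ok, , drop = FALSE]
  idx <- c(tbl$i, tbl$j)
  if (anyDuplicated(idx)) {
    keep <- !duplicated(tbl$i) & !duplicated(tbl$j) &
      !(tbl$i %in% tbl$j) & !(tbl$j %in% tbl$i[duplicated(tbl$i)])
    tbl <- tbl[keep, , drop = FALSE]
    idx <- c(tbl$i, tbl$j)
    if (anyDuplicated(idx)) {
      # drop later rows that still clash
      seen <- integer(0)
      rows <- logical(nrow(tbl))
      for (r in seq_len(nrow(tbl))) {
        if (tbl$i[r] %in% seen || tbl$j[r] %in% seen) next
        rows[r] <- TRUE
        seen <- c(seen, tbl$i[r], tbl$j[r])
      }
      tbl <- tbl[rows, , drop = FALSE]
    }
  }
  # drop nested-layer crossings greedily
  nest <- tbl[!tbl$pk, , drop = FALSE]
  nest <- nest[order(nest$i), , drop = FALSE]
  keep <- rep(TRUE, nrow(nest))
  for (a in seq_len(nrow(nest))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(nest))) {
      if (b <= a || !keep[b]) next
      if (nest$i[a] < nest$i[b] & nest$i[b] < nest$j[a] &
          nest$j[a] < nest$j[b]) keep[b] <- FALSE
    }
  }
  nest <- nest[keep, , drop = FALSE]
  # no lonely pairs: folding engines disallow isolated base pairs, and a
  # 1-pair helix would evade the two-flanking-pair eligibility rule
  if (nrow(nest) > 0L) {
    nest <- nest[order(nest$i), , drop = FALSE]
    stacked_prev <- c(FALSE, nest$i[-1] == nest$i[-nrow(nest)] + 1L &
                        nest$j[-1] == nest$j[-nrow(nest)] - 1L)
    stacked_next <- c(stacked_prev[-1], FALSE)
    nest <- nest[stacked_prev | stacked_next, , drop = FALSE]
  }
  final <- dplyr::bind_rows(nest, tbl[tbl$pk, , drop = FALSE])
  # deleted/relocated helices re-form in currently unpaired territory,
  # producing wholly false loops rather than slid copies of true ones
  for (q in seq_len(relocations)) {
    occupied <- logical(L)
    occupied[c(final$i, final$j)] <- TRUE
    free <- which(!occupied)
    if (length(free) == 0L) break
    run_id <- cumsum(c(1L, diff(free) != 1L))
    spans <- split(free, run_id)
    spans <- spans[lengths(spans) >= 13L]
    # only spans lying within one nested face keep the layer planar; a span
    # of consecutive unpaired positions always does
    if (length(spans) == 0L) break
    run <- spans[[sample(length(spans), 1)]]
    start <- run[sample(length(run) - 10L, 1)]
    # decoy loops drawn from the motif classes under study
    loop_len <- sample(c(4L, 6L), 1)
    width <- 6L + loop_len
    if (start + width - 1L > max(run)) next
    hel <- tibble::tibble(i = start + 0:2,
                          j = start + width - 1L - (0:2),
                          pk = FALSE)
    final <- dplyr::bind_rows(final, hel)
  }
  rna_structure(s$sequence, cbind(final$i, final$j), pk = final$pk,
                warn_noncanonical = FALSE)
}

#' Generate a benchmark of synthetic RNAs
#'
#' One structure + profile per RNA, each from its own derived seed, with a
#' shared motif inventory drawn from the spec.
#'
#' @param n_rna Number of RNAs.
#' @param spec A [synth_spec()].
#' @param seed Base seed; RNA r uses seeds derived as `seed + 97 * r` (+1
#'   for its profile).
#' @return Tibble with columns `rna_id`, `structure`, `profile`.
#' @export
generate_benchmark <- function(n_rna, spec = synth_spec(), seed = 1L) {
  rows <- purrr::map(seq_len(n_rna), function(r) {
    s <- generate_structure(spec, seed = seed + 97L * r)
    list(rna_id = sprintf("rna_%02d", r), structure = s,
         profile = generate_shape(s, spec, seed = seed + 97L * r + 1L))
  })
  tibble::tibble(
    rna_id = purrr::map_chr(rows, "rna_id"),
    structure = purrr::map(rows, "structure"),
    profile = purrr::map(rows, "profile")
  )
}

#' Training differences for the posterior model
#'
#' Collects pattern-pair SHAPE differences `D` from loops of the reference
#' structures (the true class) and from candidate-ensemble loops absent
#' from the references (the false class). Loop identity is exact: type,
#' unpaired positions and closing pairs. Candidate loops are de-duplicated
#' by identity within each RNA, so repeatedly sampled false loops
#' contribute one observation each.
#'
#' @param benchmark Tibble (`rna_id`, `structure`, `profile`).
#' @param ensembles Named list: `rna_id` -> list of candidate
#'   [rna_structure] objects.
#' @param patterns A pattern tibble.
#' @return List: `true` and `false` numeric difference vectors (false-loop
#'   differences de-duplicated by loop identity), plus `n_true_pairs` /
#'   `n_false_pairs` — pattern-pair counts over the ensemble *with*
#'   multiplicity, the quantities [estimate_priors()] expects (a loop
#'   sampled by many candidates weighs accordingly in the prior).
#' @export
make_training_differences <- function(benchmark, ensembles, patterns) {
  true_d <- numeric(0); false_d <- numeric(0)
  n_true_pairs <- 0L; n_false_pairs <- 0L
  for (k in seq_len(nrow(benchmark))) {
    s <- benchmark$structure[[k]]
    prof <- benchmark$profile[[k]]
    ref_loops <- extract_loops(s)
    ref_keys <- loop_keys(ref_loops)
    true_d <- c(true_d, pattern_differences(ref_loops, prof, patterns))
    ens <- ensembles[[benchmark$rna_id[k]]]
    if (is.null(ens)) next
    seen <- character(0)
    for (cand in ens) {
      cl <- extract_loops(cand)
      keys <- loop_keys(cl)
      is_true <- keys %in% ref_keys
      n_true_pairs <- n_true_pairs +
        length(pattern_differences(cl[is_true, , drop = FALSE], prof,
                                   patterns))
      n_false_pairs <- n_false_pairs +
        length(pattern_differences(cl[!is_true, , drop = FALSE], prof,
                                   patterns))
      new <- !is_true & !(keys %in% seen)
      seen <- c(seen, keys[new])
      if (any(new)) {
        false_d <- c(false_d,
                     pattern_differences(cl[new, , drop = FALSE], prof,
                                         patterns))
      }
    }
  }
  list(true = true_d, false = false_d,
       n_true_pairs = n_true_pairs, n_false_pairs = n_false_pairs)
}

#' Train a posterior model from a synthetic benchmark
#'
#' Generates candidate ensembles for every benchmark RNA, collects true and
#' false training differences and fits the posterior model with priors
#' estimated from the ensemble pair counts.
#'
#' @inheritParams make_training_differences
#' @param ensemble_size Candidates per RNA.
#' @param perturb_rate Per-helix perturbation probability.
#' @param seed Integer seed.
#' @return A `posterior_model`.
#' @export
train_posterior_model <- function(benchmark, patterns, ensemble_size = 30L,
                                  perturb_rate = 0.6, seed = 1L) {
  ens <- purrr::map(seq_len(nrow(benchmark)), function(k) {
    generate_ensemble(benchmark$structure[[k]], ensemble_size,
                      perturb_rate = perturb_rate, seed = seed + 13L * k)
  })
  names(ens) <- benchmark$rna_id
  td <- make_training_differences(benchmark, ens, patterns)
  fit_posterior_model(td$true, td$false,
                      priors = estimate_priors(td$n_true_pairs,
                                               td$n_false_pairs))
}

pattern_differences <- function(loops, profile, patterns) {
  out <- numeric(0)
  for (k in seq_len(nrow(loops))) {
    pats <- patterns[patterns$motif == loops$motif[k], , drop = FALSE]
    if (nrow(pats) == 0L) next
    mp <- motif_positions(loops$loop_type[k], loops$sides[[k]])
    d <- as.numeric(profile[mp[pats$high_pos]]) -
      as.numeric(profile[mp[pats$low_pos]])
    out <- c(out, d[!is.na(d)])
  }
  out
}

#' Shift one helix of a structure
#'
#' Moves both strands of the chosen helix by `shift` positions, dropping
#' any pair that would clash or leave the sequence. Used to plant a known
#' wrong loop in a guidance structure.
#'
#' @param s An [rna_structure].
#' @param helix_index Index into the structure's stacked-helix runs (5' order).
#' @param shift Signed shift in nucleotides.
#' @return An [rna_structure] with the helix displaced.
#' @seealso [plant_wrong_loop()] for a clash-free displacement.
#' @export
shift_helix <- function(s, helix_index, shift) {
  runs <- helix_runs(s)
  stopifnot(helix_index >= 1L, helix_index <= length(runs))
  h <- runs[[helix_index]]
  tbl <- s$pairs
  in_h <- paste(tbl$i, tbl$j) %in% paste(h$i, h$j)
  tbl$i[in_h] <- tbl$i[in_h] + shift
  tbl$j[in_h] <- tbl$j[in_h] + shift
  L <- rna_length(s)
  ok <- tbl$i >= 1L & tbl$j <= L
  tbl <- tbl[ok, , drop = FALSE]
  drop <- logical(nrow(tbl))
  seen <- integer(0)
  ord <- order(!in_h[ok]) # shifted helix wins clashes
  for (r in ord) {
    if (tbl$i[r] %in% seen || tbl$j[r] %in% seen) { drop[r] <- TRUE; next }
    seen <- c(seen, tbl$i[r], tbl$j[r])
  }
  tbl <- tbl[!drop, , drop = FALSE]
  rna_structure(s$sequence, cbind(tbl$i, tbl$j),
                pk = NULL, warn_noncanonical = FALSE)
}

#' Plant one wrong loop in a guidance structure
#'
#' Displaces a top-level stem-loop helix by `shift` nucleotides into free
#' exterior space, so that exactly one loop of the returned guidance
#' structure is wrong (its unpaired run slides onto residues that are
#' paired in the truth) while every other loop is untouched. Errors when no
#' helix has enough clash-free room.
#'
#' @param truth The true [rna_structure].
#' @param shift Displacement magnitude in nucleotides (default 3; both
#'   directions are tried).
#' @param seed Integer seed for the choice among feasible helices.
#' @return A list: `guidance` (the displaced structure) and `helix_index`
#'   (which stacked-helix run was moved).
#' @export
plant_wrong_loop <- function(truth, shift = 3L, seed = 1L) {
  runs <- helix_runs(truth)
  p <- partner_vector(truth)
  L <- rna_length(truth)
  feasible <- list()
  for (k in seq_along(runs)) {
    h <- runs[[k]]
    i_out <- min(h$i); i_in <- max(h$i)
    j_in <- min(h$j); j_out <- max(h$j)
    # standalone stem-loop: closes a hairpin directly and sits at top level
    closes_hairpin <- all(p[(i_in + 1L):(j_in - 1L)] == 0L)
    top_level <- !any(truth$pairs$i < i_out & truth$pairs$j > j_out)
    if (!closes_hairpin || !top_level) next
    for (s0 in c(shift, -shift)) {
      tgt <- if (s0 > 0L) (j_out + 1L):(j_out + s0) else (i_out + s0):(i_out - 1L)
      if (min(tgt) < 1L || max(tgt) > L) next
      if (any(p[tgt] != 0L)) next
      feasible[[length(feasible) + 1L]] <- c(k, s0)
    }
  }
  if (length(feasible) == 0L) stop("no helix with clash-free room to displace")
  pick <- withr::with_seed(seed, feasible[[sample(length(feasible), 1L)]])
  g <- shift_helix(truth, pick[1], pick[2])
  stopifnot(nrow(g$pairs) == nrow(truth$pairs))
  list(guidance = g, helix_index = pick[1], shift = pick[2])
}

#' Default synthetic benchmark conditions
#'
#' The study conditions used throughout the package's tests and examples:
#' 170-nt RNAs carrying three tetraloops, two hexaloops, a 2-nt bulge and
#' 1x2 / 2x2 internal loops (leaving standalone stem-loops available for
#' wrong-loop planting), default reactivity distributions and planted
#' offsets, 3% missing data.
#'
#' @return A [synth_spec()].
#' @export
benchmark_spec <- function() {
  synth_spec(
    rna_length = 170L,
    motifs = c("hairpin-4" = 3L, "hairpin-6" = 2L, "bulge-2" = 1L,
               "internal-1x2" = 1L, "internal-2x2" = 1L),
    missing_rate = 0.03
  )
}

#' Compact conditions for refinement trials
#'
#' Smaller RNAs (70 nt, two pattern-bearing stem-loops) used when exercising
#' guidance refinement and structure selection: few enough pattern pairs
#' that a trial isolates the selector's behaviour rather than the
#' accumulation of reactivity noise over many loops.
#'
#' @return A [synth_spec()].
#' @export
refinement_spec <- function() {
  synth_spec(
    rna_length = 70L,
    motifs = c("hairpin-4" = 1L, "hairpin-6" = 1L),
    missing_rate = 0.03
  )
}
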