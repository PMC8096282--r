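# Independent oracles used to cross-check the implementation. Each is a
# deliberately different route to the same answer (recursive descent over
# the bracket string, full sign-assignment enumeration, plain arithmetic).

# --- brute-force loop enumeration from a dot-bracket string ----------------
# Recursive descent over the parenthesis tree; classifies every face and
# applies the flanking-pair eligibility and pseudoknot exclusion rules.
# Returns a character vector of loop signatures "type|positions|closings".
oracle_loops <- function(db, pk_positions = integer()) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(ch)
  partner <- integer(n)
  st <- integer(0)
  for (k in seq_len(n)) {
    if (ch[k] == "(") st <- c(st, k)
    if (ch[k] == ")") {
      partner[k] <- st[length(st)]
      partner[st[length(st)]] <- k
      st <- st[-length(st)]
    }
  }
  sigs <- character(0)
  walk <- function(i, j) {
    # face closed by pair (i, j)
    runs <- list(); children <- list(); cur <- integer(0)
    k <- i + 1L
    while (k < j) {
      if (partner[k] == 0L) { cur <- c(cur, k); k <- k + 1L }
      else {
        runs[[length(runs) + 1L]] <- cur; cur <- integer(0)
        children[[length(children) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      }
    }
    runs[[length(runs) + 1L]] <- cur
    nc <- length(children)
    type <- NULL
    if (nc == 0L) type <- "hairpin"
    else if (nc == 1L) {
      e1 <- length(runs[[1]]) == 0L; e2 <- length(runs[[2]]) == 0L
      if (!(e1 && e2)) type <- if (e1 || e2) "bulge" else "internal"
    } else type <- "multibranch"
    if (!is.null(type)) {
      eligible <- i > 1L && j < n && partner[i - 1L] == j + 1L
      for (c0 in children) {
        eligible <- eligible && (c0[1] + 1L < c0[2]) &&
          partner[c0[1] + 1L] == c0[2] - 1L
      }
      pos <- sort(unlist(runs))
      if (eligible && !any(pos %in% pk_positions)) {
        closing <- rbind(c(i, j), do.call(rbind, children))
        sigs <<- c(sigs, paste0(type, "|", paste(pos, collapse = ","), "|",
                                paste(t(closing), collapse = ",")))
      }
    }
    for (c0 in children) walk(c0[1], c0[2])
  }
  k <- 1L
  while (k <= n) {
    if (partner[k] > k) { walk(k, partner[k]); k <- partner[k] + 1L }
    else k <- k + 1L
  }
  sort(sigs)
}

# package-side signatures in the same format
package_loop_sigs <- function(s) {
  loops <- extract_loops(s)
  sort(purrr::pmap_chr(
    list(loops$loop_type, loops$positions, loops$closing_pairs),
    function(t, p, c0) paste0(t, "|", paste(p, collapse = ","), "|",
                              paste(t(c0), collapse = ","))
  ))
}

# --- random nested dot-bracket strings, independent of the generator -------
random_nested_db <- function(len, p_open = 0.4, min_hairpin = 3L) {
  ch <- rep(".", len)
  open <- integer(0)
  for (k in seq_len(len)) {
    roll <- stats::runif(1)
    can_close <- length(open) > 0L && (k - open[length(open)]) > min_hairpin
    if (can_close && roll < 0.35) {
      ch[k] <- ")"; ch[open[length(open)]] <- "("
      open <- open[-length(open)]
    } else if (roll < 0.35 + p_open && k < len - min_hairpin) {
      open <- c(open, k) # tentatively open; stays "." unless closed
    }
  }
  paste(ch, collapse = "")
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# --- full 2^n enumeration of the signed-rank distribution ------------------
oracle_wilcoxon_p <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# --- shared fixture: trained patterns + posterior model --------------------
# Built once per test run; training conditions are the package's standard
# synthetic benchmark.
.fixture_env <- new.env(parent = emptyenv())
shared_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  bench <- generate_benchmark(12, benchmark_spec(), seed = 101)
  patterns <- discover_patterns(bench)
  model <- suppressWarnings(train_posterior_model(bench, patterns, seed = 102))
  .fixture_env$fx <- list(bench = bench, patterns = patterns, model = model)
  .fixture_env$fx
}
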