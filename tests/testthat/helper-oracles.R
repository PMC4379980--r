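# Independent oracles used by the tests. These deliberately avoid the
# package's own implementations: the genetic code comes from seqinr, tree
# fitting is done by exhaustive topology enumeration with least squares,
# and the mapping oracle scans every position of every reference.

# --- NG86 oracle ----------------------------------------------------------

oracle_aa <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

oracle_syn_sites <- function(codon) {
  a0 <- oracle_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (oracle_aa(mut) != "*" && oracle_aa(mut) == a0) s <- s + 1 / 3
    }
  }
  s
}

# enumerate every ordering of single-nucleotide steps between two codons;
# drop orderings that pass through a stop codon unless all do
oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  perms <- combinat_perms(pos)
  walk <- function(order_pos, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in order_pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && oracle_aa(nxt) == "*") return(NULL)
      syn <- oracle_aa(cur) != "*" && oracle_aa(nxt) != "*" &&
        oracle_aa(cur) == oracle_aa(nxt)
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(perms, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
        sum(vapply(cb, oracle_syn_sites, 0))) / 2
  diffs <- mapply(oracle_codon_diffs, ca, cb)
  Sd <- sum(diffs[1, ]); Nd <- sum(diffs[2, ])
  list(S = S, N = 3 * length(ca) - S, Sd = Sd, Nd = Nd,
       ps = if (S > 0) Sd / S else 0)
}

# --- exhaustive-topology NJ oracle ---------------------------------------

# enumerate all unrooted binary topologies on n labelled leaves as edge
# lists (leaves 1..n; internal nodes > n)
enumerate_topologies <- function(n) {
  start <- list(edges = rbind(c(1, n + 1), c(2, n + 1), c(3, n + 1)),
                next_node = n + 2)
  trees <- list(start)
  for (leaf in seq(4, length.out = max(0, n - 3))) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        u <- tr$edges[e, 1]; v <- tr$edges[e, 2]
        w <- tr$next_node
        edges <- rbind(tr$edges[-e, , drop = FALSE],
                       c(u, w), c(w, v), c(leaf, w))
        nxt[[length(nxt) + 1]] <- list(edges = edges, next_node = w + 1)
      }
    }
    trees <- nxt
  }
  lapply(trees, `[[`, "edges")
}

# leaves on one side of each edge (as sorted integer vectors)
edge_splits <- function(edges, n) {
  adj <- list()
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]; v <- edges[r, 2]
    adj[[as.character(u)]] <- c(adj[[as.character(u)]], v)
    adj[[as.character(v)]] <- c(adj[[as.character(v)]], u)
  }
  lapply(seq_len(nrow(edges)), function(r) {
    u <- edges[r, 1]; v <- edges[r, 2]
    # collect leaves reachable from u without crossing (u,v)
    seen <- u; stack <- u
    while (length(stack) > 0) {
      x <- stack[1]; stack <- stack[-1]
      for (y in adj[[as.character(x)]]) {
        if (x == u && y == v) next
        if (!(y %in% seen)) { seen <- c(seen, y); stack <- c(stack, y) }
      }
    }
    sort(seen[seen <= n])
  })
}

# least-squares branch fit of a topology to a distance matrix; returns the
# residual sum of squares and the split set
fit_topology <- function(edges, D) {
  n <- nrow(D)
  splits <- edge_splits(edges, n)
  pairs <- t(utils::combn(n, 2))
  A <- matrix(0, nrow(pairs), length(splits))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    for (s in seq_along(splits)) {
      A[p, s] <- (i %in% splits[[s]]) != (j %in% splits[[s]])
    }
  }
  d <- D[pairs]
  fit <- stats::lm.fit(A, d)
  list(rss = sum(fit$residuals^2), splits = splits,
       lengths = fit$coefficients)
}

# best topology for D by exhaustive search; returns its non-trivial splits
# as a set of label vectors
oracle_best_splits <- function(D) {
  n <- nrow(D)
  labs <- rownames(D)
  best <- NULL
  for (edges in enumerate_topologies(n)) {
    f <- fit_topology(edges, D)
    if (is.null(best) || f$rss < best$rss) best <- f
  }
  nt <- Filter(function(s) length(s) >= 2 && length(s) <= n - 2, best$splits)
  canon_splits(lapply(nt, function(s) labs[s]), labs)
}

# canonical form: each split as the lexicographically smaller side, sorted
canon_splits <- function(splits, labs) {
  out <- lapply(splits, function(s) {
    s <- sort(s); comp <- sort(setdiff(labs, s))
    if (paste(comp, collapse = ",") < paste(s, collapse = ",")) comp else s
  })
  sort(vapply(out, paste, "", collapse = ","))
}

phylo_splits <- function(tree) {
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)
  splits <- lapply(pp, function(idx) labs[idx])
  splits <- Filter(function(s) length(s) >= 2 && length(s) <= length(labs) - 2,
                   splits)
  canon_splits(splits, labs)
}

# --- brute-force read mapping oracle -------------------------------------

# every (reference, offset, strand) ungapped placement; accepted if the
# read is fully inside and identity >= min_id over the whole read
oracle_map_accepted <- function(reads, refs, min_id = 0.9, min_frac = 0.9) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  accepted <- character(0)
  for (rn in names(reads)) {
    rd <- reads[[rn]]
    m <- nchar(rd)
    hit <- FALSE
    for (ref in refs) {
      L <- nchar(ref)
      for (s in seq_len(max(0, L - m + 1))) {
        win <- substr(ref, s, s + m - 1)
        for (q in c(rd, rc(rd))) {
          mt <- sum(strsplit(win, "")[[1]] == strsplit(q, "")[[1]])
          if (mt / m >= min_id) hit <- TRUE
        }
        if (hit) break
      }
      if (hit) break
    }
    if (hit) accepted <- c(accepted, rn)
  }
  accepted
}

# --- repeated-window scan oracle -----------------------------------------

# maximum ungapped identity between any two windows of length `win` whose
# start separation lies in [min_sep, max_sep]
oracle_max_repeat_identity <- function(seq, win = 100, min_sep = 100,
                                       max_sep = 16000) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  best <- 0
  for (d in min_sep:min(max_sep, n - win)) {
    eq <- v[1:(n - d)] == v[(1 + d):n]
    cs <- cumsum(eq)
    runs <- cs[win:(n - d)] - c(0, cs[1:(n - d - win)])
    best <- max(best, max(runs) / win)
    if (best >= 0.8) break
  }
  best
}

# two-pass variance oracle for standard errors
oracle_se <- function(x) {
  n <- length(x)
  if (n <= 1) return(0)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1)) / sqrt(n)
}
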