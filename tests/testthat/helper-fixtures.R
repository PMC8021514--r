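# Shared fixtures, built in code at test time.

# tiny beta matrix with explicit ids
tiny_beta <- function(values, nprobe, nsample, detection_p = NULL) {
  m <- matrix(values, nprobe, nsample,
              dimnames = list(sprintf("cg%03d", seq_len(nprobe)),
                              sprintf("S%02d", seq_len(nsample))))
  beta_matrix(m, detection_p)
}

# minimal annotation covering a set of probe ids
tiny_annotation <- function(probe_ids, chromosome = "1") {
  data.frame(probe_id = probe_ids,
             chromosome = rep_len(chromosome, length(probe_ids)),
             position = seq_along(probe_ids),
             gene_symbol = NA_character_,
             cpg_type = "OpenSea", gene_region = "Intergenic",
             stringsAsFactors = FALSE)
}

# small simulated cohort shared across tests (cheap; cached per session)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 11, n_probes = 1500) {
  key <- paste0("s", seed, "_", n_probes)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_cohort(sim_config(n_probes = n_probes,
                                                    seed = seed))
  .sim_cache[[key]]
}

# independent exhaustive-enumeration oracle for Fisher's exact test:
# probabilities from binomial coefficients, two-sided by probability mass
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), 0)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# pairwise rank-statistic oracle for the AUC: P(pos on positive side) +
# half the tie probability, by explicit enumeration of all pairs
auc_rank_oracle <- function(pos, neg, direction) {
  cmp <- outer(pos, neg, `-`)
  if (direction == "positive-if-low")
    (sum(cmp < 0) + 0.5 * sum(cmp == 0)) / length(cmp)
  else
    (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
}

# exhaustive-partition oracle for the Ward objective: minimal total
# within-cluster sum of squares over all partitions of n points into k
# non-empty clusters (n small)
best_partition_wss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  assign_all <- function(n, k) {
    # all label vectors in canonical form (first occurrence order)
    out <- list(integer(0))
    for (i in seq_len(n)) {
      out <- unlist(lapply(out, function(a) {
        mx <- if (length(a)) max(a) else 0L
        lapply(seq_len(min(mx + 1L, k)), function(l) c(a, l))
      }), recursive = FALSE)
    }
    Filter(function(a) max(a) == k, out)
  }
  wss <- function(a) {
    sum(vapply(unique(a), function(l) {
      xi <- x[a == l, , drop = FALSE]
      sum(sweep(xi, 2, colMeans(xi))^2)
    }, 0))
  }
  parts <- assign_all(n, k)
  vals <- vapply(parts, wss, 0)
  list(wss = min(vals), labels = parts[[which.min(vals)]])
}
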