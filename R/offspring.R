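# Per-type single-step fate law of the branching process.
#
# Every outcome of a fate draw places `size` copies of the cell into one
# target type (division: 2 copies into the next generation; quiescence /
# advance / sink entry: 1 copy; death: none), so the offspring vector of a
# single cell is always `size * e_target`.  The moment recursions exploit
# this: E[o o^T] per type is diagonal.

# Internal: outcome table for every type.
# Returns a list (one element per type index) with components
#   prob   numeric outcome probabilities (death excluded),
#   target integer target type indices,
#   size   integer copies delivered to the target,
# plus attributes "death" (residual probability) per type.
fate_table <- function(params, topology, type_space,
                       allow_unnormalized_rho = FALSE) {
  p <- params$p
  p1 <- p + 1L
  K <- length(topology$transfer_stages)
  nsink <- length(topology$sinks)
  rho <- params$rho
  # align rho onto the topology's sink order via its rho keys
  if (nsink) {
    keys <- topology$rho_keys[topology$sinks]
    if (!all(keys %in% names(rho)))
      stop("rho is missing keys: ",
           paste(setdiff(keys, names(rho)), collapse = ", "))
    rho <- unname(rho[keys])
  }
  # type index arithmetic: j = (comp - 1) * (p + 1) + gen + 1, comps
  # ordered source (1), TR1..TRK (2..K+1), sinks (K+2..)
  D <- nrow(type_space)
  gen_of <- rep.int(0:p, D %/% p1)
  gam <- params$gamma[pmin(gen_of, length(params$gamma) - 1L) + 1L]
  del <- params$delta[pmin(gen_of, length(params$delta) - 1L) + 1L]
  if (!params$divide_at_cap) gam[gen_of == p] <- 0
  div_tgt <- seq_len(D) + ifelse(gen_of == p, 0L, 1L)
  sink_base <- (K + 1L) * p1           # sink s gen i -> sink_base+(s-1)*p1+i+1
  mig <- gen_of[seq_len(p1)] %in% params$migrating_generations
  out <- vector("list", D)
  death <- numeric(D)
  for (j in seq_len(D)) {
    comp <- (j - 1L) %/% p1 + 1L
    i <- gen_of[j]
    gi <- gam[j]; di <- del[j]
    if (comp == 1L) {                  # source
      mi <- if (mig[i + 1L]) params$m else 0
      if (mi > 0 && nsink == 0L)
        stop("migration probability is positive but the topology has no sinks")
      prob <- c(gi, di); size <- c(2L, 1L); target <- c(div_tgt[j], j)
      if (mi > 0) {
        if (K >= 2L) {                 # egress covers transit leg 1 -> stage 2
          prob <- c(prob, mi); size <- c(size, 1L)
          target <- c(target, 2L * p1 + i + 1L)
        } else {                       # 1-step transit: egress ends at the split
          prob <- c(prob, mi * rho); size <- c(size, rep(1L, nsink))
          target <- c(target, sink_base + (seq_len(nsink) - 1L) * p1 + i + 1L)
        }
      }
      resid <- 1 - gi - di - mi
      if (resid < -1e-12)
        stop(sprintf("gamma_%d + delta_%d + m_%d = %.6g > 1", i, i, i,
                     gi + di + mi))
    } else if (comp <= K + 1L) {       # transfer stage k = comp - 1
      last <- comp == K + 1L
      if (last && !allow_unnormalized_rho && abs(sum(rho) - 1) > 1e-12)
        stop("splitting probabilities must sum to 1")
      nxt_prob <- if (last) rho else 1
      nxt_idx <- if (last) sink_base + (seq_len(nsink) - 1L) * p1 + i + 1L
                 else j + p1
      if (!params$proliferate_in_transit) {
        prob <- nxt_prob; target <- nxt_idx
        size <- rep(1L, length(nxt_idx))
        resid <- 1 - sum(prob)
      } else {
        di_gen <- min(i + 1L, p)
        nxt_div <- nxt_idx + (di_gen - i)
        prob <- c(gi * nxt_prob, di * nxt_prob)
        target <- c(nxt_div, nxt_idx)
        size <- c(rep(2L, length(nxt_idx)), rep(1L, length(nxt_idx)))
        resid <- 1 - (gi + di) * sum(nxt_prob)
      }
      if (resid < -1e-12 && !allow_unnormalized_rho)
        stop(sprintf("fate probabilities of (%s, %d) exceed 1",
                     type_space$compartment[j], i))
    } else {                           # sink: proliferate in place
      prob <- c(gi, di); size <- c(2L, 1L); target <- c(div_tgt[j], j)
      resid <- 1 - gi - di
      if (resid < -1e-12)
        stop(sprintf("gamma_%d + delta_%d = %.6g > 1 in sink %s", i, i,
                     gi + di, type_space$compartment[j]))
    }
    keep <- prob > 0
    out[[j]] <- list(prob = prob[keep], target = target[keep],
                     size = size[keep])
    death[j] <- max(resid, 0)
  }
  attr(out, "death") <- death
  attr(out, "type_space") <- type_space
  out
}

#' Single-cell offspring distribution of a type
#'
#' The per-step fate law of one cell of the given (compartment,
#' generation) type: division into two next-generation cells, quiescence,
#' migration/advance along the transfer line, sink entry with the
#' splitting probabilities, or death.  Probabilities sum to 1 exactly
#' (death carries the residual mass).
#'
#' @param compartment compartment label.
#' @param generation generation (0-based).
#' @param params an `mgw_parameters`.
#' @param topology an `mgw_topology`.
#' @return data.frame with columns `outcome`, `prob`,
#'   `target_compartment`, `target_generation`, `n_offspring`; the death
#'   row has `NA` targets and 0 offspring.
#' @examples
#' offspring_distribution("DR", 0, default_parameters(), network_topology())
#' @export
offspring_distribution <- function(compartment, generation, params, topology) {
  ts <- build_type_space(topology, params$p)
  j <- type_index(ts, compartment, generation)
  ft <- fate_table(params, topology, ts)
  f <- ft[[j]]
  lab <- function(size, tc, tg) {
    ifelse(size == 2L, "divide",
      ifelse(tc == compartment, "quiesce",
        ifelse(tc %in% topology$sinks & compartment != topology$source,
               "enter_sink",
          ifelse(compartment == topology$source & tc != compartment,
                 "migrate", "advance"))))
  }
  tc <- ts$compartment[f$target]; tg <- ts$generation[f$target]
  data.frame(
    outcome = c(lab(f$size, tc, tg), "die"),
    prob = c(f$prob, 1 - sum(f$prob)),
    target_compartment = c(tc, NA),
    target_generation = c(tg, NA),
    n_offspring = c(f$size, 0L),
    stringsAsFactors = FALSE)
}

#' Mean offspring matrix of the process
#'
#' `M[j, k]` is the expected number of type-`k` offspring produced in one
#' step by one type-`j` cell; the mean count vector evolves as
#' `mu(n + 1) = t(M) %*% mu(n)`.
#'
#' @inheritParams offspring_distribution
#' @param allow_unnormalized_rho tolerate `sum(rho) != 1` (used by the
#'   sensitivity statistic, which perturbs single coordinates).
#' @return D x D matrix with type labels as dimnames.
#' @export
offspring_mean_matrix <- function(params, topology,
                                  allow_unnormalized_rho = FALSE) {
  ts <- build_type_space(topology, params$p)
  ft <- fate_table(params, topology, ts, allow_unnormalized_rho)
  moment_matrices(ft, nrow(ts), attr(ts, "labels"))$M
}

# Internal: M (mean) and Q (second factorial-ish moment, Q[j,t] = sum of
# p * size^2 over outcomes of j targeting t) from a fate table.
moment_matrices <- function(ft, D, labels = NULL) {
  M <- matrix(0, D, D); Q <- matrix(0, D, D)
  lens <- lengths(lapply(ft, `[[`, "prob"))
  js <- rep.int(seq_len(D), lens)
  tg <- unlist(lapply(ft, `[[`, "target"), use.names = FALSE)
  pr <- unlist(lapply(ft, `[[`, "prob"), use.names = FALSE)
  sz <- unlist(lapply(ft, `[[`, "size"), use.names = FALSE)
  if (length(js)) {
    key <- (tg - 1L) * D + js           # accumulate duplicate (j, target)
    mv <- rowsum(pr * sz, key); qv <- rowsum(pr * sz * sz, key)
    at <- as.integer(rownames(mv))
    M[at] <- mv
    Q[at] <- qv
  }
  if (!is.null(labels)) dimnames(M) <- dimnames(Q) <- list(labels, labels)
  list(M = M, Q = Q)
}

#' Offspring covariance matrix of one type
#'
#' Covariance of the random offspring vector of a single type-`j` cell:
#' `V_j = sum_k p_k o_k o_k^T - mu_j mu_j^T` over the fate outcomes `o_k`,
#' with `mu_j` the corresponding row of the mean matrix.  Deterministic
#' fates (pure delay stages) have `V_j = 0`.
#'
#' @inheritParams offspring_distribution
#' @return D x D symmetric positive semidefinite matrix.
#' @export
offspring_covariance <- function(compartment, generation, params, topology) {
  ts <- build_type_space(topology, params$p)
  j <- type_index(ts, compartment, generation)
  ft <- fate_table(params, topology, ts)
  f <- ft[[j]]
  D <- nrow(ts)
  mu <- numeric(D)
  EooT <- matrix(0, D, D)
  for (k in seq_along(f$prob)) {
    t <- f$target[k]
    mu[t] <- mu[t] + f$prob[k] * f$size[k]
    EooT[t, t] <- EooT[t, t] + f$prob[k] * f$size[k]^2
  }
  V <- EooT - tcrossprod(mu)
  dimnames(V) <- list(attr(ts, "labels"), attr(ts, "labels"))
  V
}
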