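# Fixed-topology likelihood engine: Felsenstein pruning with
# discrete-gamma rate heterogeneity, per-site log-likelihoods, and
# branch-length optimization by monotone coordinate ascent.
#
# Partial likelihoods are rescaled per node (per-site max) with the log
# of the scaler accumulated separately, so long alignments do not
# underflow; results agree with unscaled arithmetic wherever the latter
# is representable.

col_max <- function(X) do.call(pmax.int, lapply(seq_len(nrow(X)), function(i) X[i, ]))

# log(mean(exp(...))) across gamma categories, rows = categories
log_mean_exp <- function(M) {
  m <- do.call(pmax.int, lapply(seq_len(nrow(M)), function(i) M[i, ]))
  out <- rep(-Inf, ncol(M))
  ok <- is.finite(m)
  if (any(ok)) {
    sh <- sweep(M[, ok, drop = FALSE], 2, m[ok])
    out[ok] <- m[ok] + log(colMeans(exp(sh)))
  }
  out
}

# Normalise the models argument to one entry per partition name.
resolve_models <- function(aln, models) {
  parts <- aln$partitions
  if (is.null(parts))
    parts <- data.frame(name = "all", start = 1L, end = ncol(aln$matrix))
  if (inherits(models, "subst_model")) {
    models <- stats::setNames(rep(list(models), nrow(parts)), parts$name)
  }
  if (is.null(names(models)) || !all(parts$name %in% names(models)))
    stopf("models must be a subst_model or a named list covering every partition")
  miss <- vapply(parts$name, function(p) models[[p]]$alphabet != aln$alphabet, TRUE)
  if (any(miss)) stopf("model alphabet does not match alignment alphabet")
  list(parts = parts, models = models[parts$name])
}

# Precompute everything reused across likelihood evaluations: a
# postorder tree skeleton and, per group of partitions sharing one
# model, the tip partial matrices for the concatenated columns.
prepare_engine <- function(aln, tree, models) {
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  miss <- setdiff(tree$tip.label, rownames(aln$matrix))
  if (length(miss)) stopf("taxon in tree absent from alignment: %s", miss[1])

  rm <- resolve_models(aln, models)
  parts <- rm$parts; models <- rm$models

  # group partitions that share a model so pruning runs once per model
  uniq <- list(); gid <- integer(nrow(parts))
  for (i in seq_len(nrow(parts))) {
    hit <- 0L
    for (j in seq_along(uniq)) if (identical(uniq[[j]], models[[i]])) { hit <- j; break }
    if (!hit) { uniq[[length(uniq) + 1L]] <- models[[i]]; hit <- length(uniq) }
    gid[i] <- hit
  }

  tree2 <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree2$tip.label)
  nnode <- ntip + tree2$Nnode
  root <- tree2$edge[nrow(tree2$edge), 1]

  groups <- lapply(seq_along(uniq), function(j) {
    model <- uniq[[j]]
    cols <- unlist(Map(seq.int, parts$start[gid == j], parts$end[gid == j]))
    sets <- state_sets(aln$alphabet)
    nst <- length(model$states)
    lut_names <- names(sets)
    lut <- matrix(0, nst, length(sets))
    for (s in seq_along(sets)) lut[sets[[s]], s] <- 1
    tipP <- vector("list", ntip)
    for (tp in seq_len(ntip)) {
      chars <- aln$matrix[tree2$tip.label[tp], cols]
      idx <- match(chars, lut_names)
      idx[is.na(idx)] <- match("-", lut_names)
      tipP[[tp]] <- lut[, idx, drop = FALSE]
    }
    list(model = model, cols = cols, tipP = tipP)
  })

  list(tree = tree2, ntip = ntip, nnode = nnode, root = root,
       parts = parts, groups = groups, n_sites = ncol(aln$matrix))
}

# transition matrix from a prepared model at branch length t and rate r
edge_P <- function(model, t, r) {
  e <- model$eig
  P <- e$U %*% (exp(e$values * t * r) * e$Uinv)
  P[P < 0] <- 0
  P
}

# Postorder partials for one model group and one category, with
# per-site rescaling as each internal node accumulates its children.
# With keep_msgs, the per-edge products P %*% part[child] (the upward
# messages) are also returned for reuse by the optimizer.
group_partials <- function(eng, g, rate, keep_msgs = FALSE) {
  tree <- eng$tree; model <- g$model
  ns <- length(model$states); S <- length(g$cols)
  part <- vector("list", eng$nnode)
  scal <- vector("list", eng$nnode)
  msgs <- if (keep_msgs) vector("list", nrow(tree$edge))
  zero <- rep(0, S)
  for (tp in seq_len(eng$ntip)) { part[[tp]] <- g$tipP[[tp]]; scal[[tp]] <- zero }
  edge <- tree$edge; el <- tree$edge.length
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    M <- edge_P(model, el[k], rate) %*% part[[ch]]
    if (keep_msgs) msgs[[k]] <- list(M = M, scal = scal[[ch]])
    if (is.null(part[[p]])) { part[[p]] <- M; scal[[p]] <- scal[[ch]] }
    else { part[[p]] <- part[[p]] * M; scal[[p]] <- scal[[p]] + scal[[ch]] }
    mx <- col_max(part[[p]])
    mx[mx <= 0] <- 1
    part[[p]] <- part[[p]] / rep(mx, each = ns)
    scal[[p]] <- scal[[p]] + log(mx)
  }
  list(part = part, scal = scal, msgs = msgs)
}

# Per-site log-likelihood for one model group (all categories merged).
group_site_ll <- function(eng, g) {
  model <- g$model
  k <- model$n_categories
  out <- matrix(NA_real_, k, length(g$cols))
  for (c in seq_len(k)) {
    gp <- group_partials(eng, g, model$rates[c])
    rv <- colSums(model$pi * gp$part[[eng$root]])
    ll <- ifelse(rv > 0, log(rv), -Inf) + gp$scal[[eng$root]]
    out[c, ] <- ll
  }
  log_mean_exp(out)
}

#' Per-site log-likelihoods on a fixed topology
#'
#' Felsenstein pruning with discrete-gamma rate heterogeneity (equal
#' category weights). Gaps and ambiguity codes contribute a partial
#' vector of ones over their compatible states (fully missing for
#' `-`/`?`/`X`). The sum over sites equals the total log-likelihood.
#'
#' @param aln an [alignment()]; its taxa must include all tree tips.
#' @param tree a `phylo` with branch lengths.
#' @param models a single [build_model()] object, or a named list with
#'   one model per partition of `aln`.
#' @return numeric vector of per-site log-likelihoods (nats), one per
#'   alignment column, with the site's partition as attribute
#'   `"partition"`. Sites whose likelihood is exactly zero (conflicting
#'   fixed states across a zero-length path) come back `-Inf` with a
#'   warning.
#' @export
site_log_likelihoods <- function(aln, tree, models) {
  eng <- prepare_engine(aln, tree, models)
  out <- rep(NA_real_, eng$n_sites)
  for (g in eng$groups) out[g$cols] <- group_site_ll(eng, g)
  if (any(is.infinite(out)))
    warning("some sites have zero likelihood (reported as -Inf)", call. = FALSE)
  attr(out, "partition") <- site_partition(aln)
  out
}

#' Total log-likelihood of an alignment on a fixed tree
#' @inheritParams site_log_likelihoods
#' @return total log-likelihood in nats.
#' @export
total_log_likelihood <- function(aln, tree, models) {
  x <- site_log_likelihoods(aln, tree, models)
  attributes(x) <- NULL
  sum(x)
}

#' Sitewise scores of several candidate topologies
#'
#' Scores the same alignment on each tree of a named list and returns
#' the per-site log-likelihood table that the topology-contrast
#' functions consume.
#'
#' @inheritParams site_log_likelihoods
#' @param trees named list of `phylo` objects (e.g. `list(mt = ..., nuc = ...)`).
#' @return data frame with columns `site`, `partition`, and one
#'   `ll_<label>` column per tree.
#' @export
site_score_table <- function(aln, trees, models) {
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    stopf("trees must be a named list")
  out <- data.frame(site = seq_len(ncol(aln$matrix)),
                    partition = site_partition(aln))
  for (lab in names(trees)) {
    v <- site_log_likelihoods(aln, trees[[lab]], models)
    attributes(v) <- NULL
    out[[paste0("ll_", lab)]] <- v
  }
  out
}

## branch-length optimization ----------------------------------------------

# Objective for one edge: with A = above-partial (root side, siblings
# folded in) and D = below-partial, the per-site likelihood at branch
# length t is colSums(A * (P(t) %*% D)).  Through the model eigensystem
# this reduces to crossprod(GW, exp(lambda t r)) with GW the
# elementwise product of t(U) A and Uinv D, so each 1-D search step is
# one matrix-vector product per category.  `cache` is nested
# [[group]][[category]].
# The per-category scalers do not depend on t, so they are folded into
# fixed per-site weights w_c = exp(scal_c - max_c scal_c)/k once per
# edge; the objective is then sum(log(sum_c w_c x_c)) + const.
edge_site_ll <- function(cache, t) {
  tot <- 0
  for (gc in cache) {
    acc <- 0
    for (c in seq_along(gc$GW))
      acc <- acc + gc$w[[c]] * as.vector(crossprod(gc$GW[[c]], exp(gc$lam[[c]] * t)))
    tot <- tot + sum(log(pmax(acc, 1e-300))) + gc$base
  }
  tot
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate ascent: each branch in turn is optimized by a bounded 1-D
#' Brent search while all others are held fixed, sweeping the tree in
#' passes until the total log-likelihood improves by less than `tol`.
#' Every accepted move maximizes the exact current likelihood for that
#' branch, so the total log-likelihood never decreases.
#'
#' @inheritParams site_log_likelihoods
#' @param topology a `phylo`; starting branch lengths are used if
#'   present, otherwise initialised at 0.1.
#' @param max_passes maximum number of full sweeps (default 50).
#' @param tol stop when a sweep improves the total log-likelihood by
#'   less than this (default 1e-6 nats).
#' @param bounds search interval for each branch length.
#' @return the tree with optimized `edge.length`, with attributes
#'   `loglik` (total log-likelihood) and `converged` (FALSE when the
#'   pass budget ran out first).
#' @export
optimize_branch_lengths <- function(aln, topology, models, max_passes = 50L,
                                    tol = 1e-6, bounds = c(1e-8, 10)) {
  if (is.null(topology$edge.length))
    topology$edge.length <- rep(0.1, nrow(topology$edge))
  topology$edge.length <- pmin(pmax(topology$edge.length, bounds[1]), bounds[2])
  eng <- prepare_engine(aln, topology, models)
  tree <- eng$tree
  ntip <- eng$ntip; root <- eng$root
  edge <- tree$edge
  kids <- split(seq_len(nrow(edge)), edge[, 1])  # edge rows by parent node

  total_ll <- function() {
    s <- 0
    for (g in eng$groups) s <- s + sum(group_site_ll(eng, g))
    s
  }
  prev <- total_ll()
  converged <- FALSE

  for (pass in seq_len(max_passes)) {
    # fresh postorder partials (all categories, all groups); the edge
    # messages fall out of the same sweep
    D <- lapply(eng$groups, function(g)
      lapply(seq_len(g$model$n_categories), function(c)
        group_partials(eng, g, g$model$rates[c], keep_msgs = TRUE)))
    Msg <- lapply(seq_len(nrow(edge)), function(k)
      lapply(seq_along(eng$groups), function(gi)
        lapply(seq_len(eng$groups[[gi]]$model$n_categories), function(c)
          D[[gi]][[c]]$msgs[[k]])))
    calc_msg <- function(k) {
      lapply(seq_along(eng$groups), function(gi) {
        g <- eng$groups[[gi]]
        lapply(seq_len(g$model$n_categories), function(c) {
          P <- edge_P(g$model, eng$tree$edge.length[k], g$model$rates[c])
          list(M = P %*% D[[gi]][[c]]$part[[edge[k, 2]]],
               scal = D[[gi]][[c]]$scal[[edge[k, 2]]])
        })
      })
    }

    # preorder walk carrying the above-partial of each visited node
    Anode <- vector("list", eng$nnode)   # [[node]][[group]][[cat]] list(A, scal)
    Anode[[root]] <- lapply(eng$groups, function(g)
      lapply(seq_len(g$model$n_categories), function(c)
        list(A = matrix(g$model$pi, length(g$model$states), length(g$cols)),
             scal = rep(0, length(g$cols)))))
    stack <- root
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      for (k in kids[[as.character(v)]]) {
        ch <- edge[k, 2]
        sib <- setdiff(kids[[as.character(v)]], k)
        # A for this edge = above(v) * prod of sibling messages
        cache <- vector("list", length(eng$groups))
        Aedge <- vector("list", length(eng$groups))
        for (gi in seq_along(eng$groups)) {
          g <- eng$groups[[gi]]
          nk <- g$model$n_categories
          Aedge[[gi]] <- vector("list", nk)
          GWs <- vector("list", nk); lams <- vector("list", nk)
          scals <- matrix(0, nk, length(g$cols))
          for (c in seq_len(nk)) {
            A <- Anode[[v]][[gi]][[c]]$A
            sc <- Anode[[v]][[gi]][[c]]$scal
            for (s in sib) {
              A <- A * Msg[[s]][[gi]][[c]]$M
              sc <- sc + Msg[[s]][[gi]][[c]]$scal
            }
            Aedge[[gi]][[c]] <- list(A = A, scal = sc)
            e <- g$model$eig
            GWs[[c]] <- crossprod(e$U, A) * (e$Uinv %*% D[[gi]][[c]]$part[[ch]])
            lams[[c]] <- e$values * g$model$rates[c]
            scals[c, ] <- sc + D[[gi]][[c]]$scal[[ch]]
          }
          m <- do.call(pmax.int, lapply(seq_len(nk), function(i) scals[i, ]))
          cache[[gi]] <- list(
            GW = GWs, lam = lams,
            w = lapply(seq_len(nk), function(i) exp(scals[i, ] - m) / nk),
            base = sum(m))
        }
        t0 <- eng$tree$edge.length[k]
        f0 <- edge_site_ll(cache, t0)
        op <- stats::optimize(function(t) edge_site_ll(cache, t),
                              interval = bounds, maximum = TRUE, tol = 1e-6)
        cand <- c(op$maximum, bounds[1])
        fv <- c(op$objective, edge_site_ll(cache, bounds[1]))
        best <- which.max(fv)
        if (fv[best] > f0) {
          eng$tree$edge.length[k] <- cand[best]
          Msg[[k]] <- calc_msg(k)
          cur_total <- fv[best]
        } else cur_total <- f0
        # descend: above-partial of the child node
        if (ch > ntip) {
          Anode[[ch]] <- vector("list", length(eng$groups))
          for (gi in seq_along(eng$groups)) {
            g <- eng$groups[[gi]]
            Anode[[ch]][[gi]] <- vector("list", g$model$n_categories)
            for (c in seq_len(g$model$n_categories)) {
              P <- edge_P(g$model, eng$tree$edge.length[k], g$model$rates[c])
              A2 <- crossprod(P, Aedge[[gi]][[c]]$A)
              mx <- col_max(A2); mx[mx <= 0] <- 1
              A2 <- A2 / rep(mx, each = nrow(A2))
              Anode[[ch]][[gi]][[c]] <-
                list(A = A2, scal = Aedge[[gi]][[c]]$scal + log(mx))
            }
          }
          stack <- c(stack, ch)
        }
      }
    }
    # the last edge's accepted objective is the exact current total LL
    cur <- cur_total
    if (cur - prev < tol) { converged <- TRUE; prev <- max(cur, prev); break }
    prev <- cur
  }

  out <- eng$tree
  attr(out, "loglik") <- prev
  attr(out, "converged") <- converged
  out
}
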