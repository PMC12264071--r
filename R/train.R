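#' Training configuration
#'
#' Defaults follow the reference schedule: stochastic gradient descent with
#' batch size 20, initial learning rate 0.01 decreased by a factor of 10
#' every 10 epochs, weights initialized from `N(0, 0.01^2)`, 50 epochs for
#' the single-modal stages. The fusion stage is typically run for fewer
#' epochs (see [fit_fusion()]).
#'
#' @param batch_size Minibatch size (default 20). Risk sets for the partial
#'   likelihood are formed within each minibatch.
#' @param lr0 Initial learning rate (default 0.01).
#' @param lr_decay Multiplicative decay factor (default 0.1).
#' @param lr_step Epochs between decays (default 10).
#' @param epochs Number of epochs (default 50).
#' @param init_sd Weight initialization standard deviation (default 0.01).
#' @param weight_decay L2 penalty on weight matrices, Cox-nnet-style ridge
#'   (default 1e-4; biases are not penalized).
#' @param seed Master seed for initialization and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 20L, lr0 = 0.01, lr_decay = 0.1,
                         lr_step = 10L, epochs = 50L, init_sd = 0.01,
                         weight_decay = 1e-4, seed = 1L) {
  stopifnot(batch_size >= 2, lr0 > 0, lr_decay > 0, lr_step >= 1,
            epochs >= 1, init_sd > 0, weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 epochs = as.integer(epochs), init_sd = init_sd,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given (0-based) epoch
#'
#' `lr0 * lr_decay^(epoch %/% lr_step)`: 0.01 for epochs 0-9, 0.001 for
#' 10-19, and so on at the defaults.
#'
#' @param cfg A [train_config()].
#' @param epoch 0-based epoch index.
#' @return Scalar learning rate.
#' @export
lr_at <- function(cfg, epoch) {
  cfg$lr0 * cfg$lr_decay^(epoch %/% cfg$lr_step)
}

# SGD step with L2 decay on matrices named W* (never on biases)
sgd_update <- function(params, grads, lr, wd) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (wd > 0 && startsWith(nm, "W")) g <- g + wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * g
  }
  params
}

zero_like <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

make_batches <- function(ids, batch_size) {
  split(ids, ceiling(seq_along(ids) / batch_size))
}

surv_of <- function(cohort, ids) {
  s <- cohort$survival
  s[match(ids, s$patient_id), , drop = FALSE]
}

# ---- graph stage ---------------------------------------------------------

standardize_stats <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

apply_standardize <- function(X, std) {
  sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")
}

#' Fit the graph (histology) branch
#'
#' Trains the GCN encoder plus a linear Cox head on the patients' nuclei
#' graphs. Node attributes are z-scored with training-set statistics
#' (stored in the checkpoint); a patient's score is the head applied to the
#' mean of their tile embeddings; the loss is the within-batch negative Cox
#' partial log-likelihood, normalized by the number of events in the batch.
#'
#' @param cohort A cohort (see [make_cohort()]) with `graphs` and `survival`.
#' @param gcn_cfg A [gcn_config()].
#' @param cfg A [train_config()].
#' @param ids Patient ids to train on (default: all with graphs).
#' @return A checkpoint list: `stage`, `gcn_cfg`, `params`, `head`, `std`,
#'   `train_cfg`, `loss_log` (mean per-event loss per epoch).
#' @export
fit_graph_branch <- function(cohort, gcn_cfg = gcn_config(),
                             cfg = train_config(), ids = NULL) {
  if (is.null(ids)) ids <- names(cohort$graphs)
  stopifnot(length(ids) >= 2, all(ids %in% names(cohort$graphs)))
  graphs <- cohort$graphs[ids]

  all_attrs <- do.call(rbind, lapply(graphs, function(gl)
    do.call(rbind, lapply(gl, `[[`, "node_attrs"))))
  std <- standardize_stats(all_attrs)
  prepped <- lapply(graphs, function(gl) lapply(gl, function(g)
    list(attrs = apply_standardize(g$node_attrs, std), edges = g$edges,
         ops = graph_ops(g$edges, nrow(g$node_attrs)))))

  in_dim <- ncol(all_attrs)
  params <- gcn_init(in_dim, gcn_cfg, seed = derive_seed(cfg$seed, "gcn_init"),
                     sd = cfg$init_sd)
  head <- with_seed(derive_seed(cfg$seed, "gcn_head"),
                    list(w = stats::rnorm(gcn_cfg$out_dim, 0, cfg$init_sd), b = 0))

  surv <- surv_of(cohort, ids)
  loss_log <- numeric(cfg$epochs)
  set.seed(derive_seed(cfg$seed, "gcn_sgd"))
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at(cfg, epoch)
    perm <- sample(ids)
    tot_loss <- 0; tot_events <- 0
    for (batch in make_batches(perm, cfg$batch_size)) {
      sb <- surv_of(cohort, batch)
      ne <- sum(sb$event)
      caches <- lapply(batch, function(pid)
        lapply(prepped[[pid]], function(g)
          gcn_forward_cached(g$attrs, g$edges, gcn_cfg, params, ops = g$ops)))
      zbar <- t(vapply(caches, function(cl)
        rowMeans(vapply(cl, `[[`, numeric(gcn_cfg$out_dim), "z")),
        numeric(gcn_cfg$out_dim)))
      theta <- as.vector(zbar %*% head$w + head$b)
      if (ne == 0) next
      tot_loss <- tot_loss + cox_pll_loss(theta, sb$time, sb$event)
      tot_events <- tot_events + ne
      gtheta <- cox_pll_grad(theta, sb$time, sb$event) / ne

      gW_head <- as.vector(crossprod(zbar, gtheta))
      gb_head <- sum(gtheta)
      grads <- zero_like(params)
      for (pi in seq_along(batch)) {
        m <- length(caches[[pi]])
        gz <- gtheta[pi] * head$w / m
        for (cc in caches[[pi]])
          grads <- add_grads(grads, gcn_backward(cc, gcn_cfg, params, gz))
      }
      params <- sgd_update(params, grads, lr, cfg$weight_decay)
      head$w <- head$w - lr * (gW_head + cfg$weight_decay * head$w)
      head$b <- head$b - lr * gb_head
    }
    loss_log[epoch + 1L] <- if (tot_events > 0) tot_loss / tot_events else NA_real_
  }
  list(stage = "graph", gcn_cfg = gcn_cfg, params = params, head = head,
       std = std, train_cfg = cfg, loss_log = loss_log)
}

# mean tile embedding of one patient under a fitted graph checkpoint
embed_graph_patient <- function(ckpt, graph_list) {
  zs <- lapply(graph_list, function(g)
    gcn_forward_cached(apply_standardize(g$node_attrs, ckpt$std), g$edges,
                       ckpt$gcn_cfg, ckpt$params)$z)
  patient_embedding(zs)
}

# ---- omics stage ---------------------------------------------------------

# Training-scale design matrices: expression on log2(x+1) z-scores,
# methylation on M-value z-scores, mutation centered 0/1.
omics_design <- function(bundle, ids, prep = NULL) {
  ex <- log2(unclass(bundle$expression)[ids, , drop = FALSE] + 1)
  mu <- unclass(bundle$mutation)[ids, , drop = FALSE]
  me <- unclass(beta_to_m(bundle$methylation))[ids, , drop = FALSE]
  if (is.null(prep)) {
    prep <- list(expression = standardize_stats(ex),
                 methylation = standardize_stats(me),
                 mutation = list(mean = colMeans(mu)))
  }
  list(x = list(expression = apply_standardize(ex, prep$expression),
                mutation = sweep(mu, 2, prep$mutation$mean, "-"),
                methylation = apply_standardize(me, prep$methylation)),
       prep = prep)
}

#' Fit the multiomics branch
#'
#' Trains the three parallel MLPs plus a linear Cox head. Expression enters
#' as z-scored `log2(x + 1)`, methylation as z-scored M-values, mutation as
#' centered 0/1 indicators; the transforms' training statistics are stored
#' in the checkpoint.
#'
#' @param cohort A cohort with `omics` (an `omics_bundle`) and `survival`.
#' @param omics_cfg An [omics_config()].
#' @param cfg A [train_config()].
#' @param ids Training patient ids (default: all in the bundle).
#' @return A checkpoint list (`stage = "omics"`).
#' @export
fit_omics_branch <- function(cohort, omics_cfg = omics_config(),
                             cfg = train_config(), ids = NULL) {
  if (is.null(ids)) ids <- rownames(cohort$omics$expression)
  des <- omics_design(cohort$omics, ids)
  in_dims <- vapply(des$x, ncol, integer(1))
  params <- omics_init(in_dims, omics_cfg,
                       seed = derive_seed(cfg$seed, "omics_init"),
                       sd = cfg$init_sd)
  head <- with_seed(derive_seed(cfg$seed, "omics_head"),
                    list(w = stats::rnorm(omics_cfg$shared_dim, 0, cfg$init_sd),
                         b = 0))
  mods <- c("expression", "mutation", "methylation")
  loss_log <- numeric(cfg$epochs)
  set.seed(derive_seed(cfg$seed, "omics_sgd"))
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at(cfg, epoch)
    perm <- sample(ids)
    tot_loss <- 0; tot_events <- 0
    for (batch in make_batches(perm, cfg$batch_size)) {
      sb <- surv_of(cohort, batch)
      ne <- sum(sb$event)
      if (ne == 0) next
      ridx <- match(batch, ids)
      fws <- lapply(mods, function(m)
        mlp_forward(des$x[[m]][ridx, , drop = FALSE], params[[m]]))
      names(fws) <- mods
      z <- Reduce(`+`, lapply(fws, `[[`, "out"))
      if (omics_cfg$combine == "mean") z <- z / 3
      theta <- as.vector(z %*% head$w + head$b)
      tot_loss <- tot_loss + cox_pll_loss(theta, sb$time, sb$event)
      tot_events <- tot_events + ne
      gtheta <- cox_pll_grad(theta, sb$time, sb$event) / ne

      gz <- gtheta %o% head$w
      if (omics_cfg$combine == "mean") gz <- gz / 3
      for (m in mods) {
        gl <- mlp_backward(fws[[m]], params[[m]], gz)
        for (l in seq_along(params[[m]])) {
          params[[m]][[l]]$W <- params[[m]][[l]]$W -
            lr * (gl[[l]]$W + cfg$weight_decay * params[[m]][[l]]$W)
          params[[m]][[l]]$b <- params[[m]][[l]]$b - lr * gl[[l]]$b
        }
      }
      head$w <- head$w - lr * (as.vector(crossprod(z, gtheta)) +
                                 cfg$weight_decay * head$w)
      head$b <- head$b - lr * sum(gtheta)
    }
    loss_log[epoch + 1L] <- if (tot_events > 0) tot_loss / tot_events else NA_real_
  }
  list(stage = "omics", omics_cfg = omics_cfg, params = params, head = head,
       prep = des$prep, train_cfg = cfg, loss_log = loss_log)
}

embed_omics_patients <- function(ckpt, bundle, ids) {
  des <- omics_design(bundle, ids, prep = ckpt$prep)
  z <- omics_forward(des$x, ckpt$omics_cfg, ckpt$params)
  rownames(z) <- ids
  z
}

# ---- fusion stage --------------------------------------------------------

#' Fit the tensor-fusion model
#'
#' Takes pretrained single-modal checkpoints, computes each patient's frozen
#' embeddings `z_g` and `z_o`, fuses them by [tensor_fuse()] and trains the
#' hazard head `theta = <W, Z> + b` (output dimension 1) on the flattened
#' fused tensor against the Cox partial likelihood. By default the head is
#' the plain linear map of the fusion equation and its unimodal entries —
#' the first row and column of the fused tensor, which carry `z_o` and
#' `z_g` unchanged — are initialized from the pretrained single-modal head
#' weights (interaction entries start at the usual Gaussian init), so the
#' fusion model begins where the single-modal models left off and SGD
#' refines the multiplicative interactions. A Cox-nnet-style tanh hidden
#' layer is available via `use_hidden`. Fused features are z-scored with
#' training statistics stored in the checkpoint.
#'
#' @param cohort A cohort with graphs, omics and survival.
#' @param graph_ckpt,omics_ckpt Checkpoints from [fit_graph_branch()] and
#'   [fit_omics_branch()]; both are required.
#' @param cfg A [train_config()].
#' @param hidden_dim Width of the optional hidden layer (default 8).
#' @param use_hidden Include the hidden layer (default FALSE: the linear
#'   fusion equation).
#' @param init_from_heads Transplant single-modal head weights into the
#'   unimodal blocks at initialization (default TRUE; linear head only).
#' @param ids Training patient ids.
#' @return A checkpoint list (`stage = "fusion"`) embedding both branch
#'   checkpoints.
#' @export
fit_fusion <- function(cohort, graph_ckpt, omics_ckpt, cfg = train_config(),
                       hidden_dim = 8L, use_hidden = FALSE,
                       init_from_heads = TRUE, ids = NULL) {
  if (missing(graph_ckpt) || is.null(graph_ckpt) ||
      missing(omics_ckpt) || is.null(omics_ckpt))
    stop("fusion stage requires pretrained graph and omics checkpoints")
  if (is.null(ids))
    ids <- intersect(names(cohort$graphs), rownames(cohort$omics$expression))
  X <- fused_design(cohort, graph_ckpt, omics_ckpt, ids)
  std <- standardize_stats(X)
  Xs <- apply_standardize(X, std)
  d <- ncol(Xs)

  params <- with_seed(derive_seed(cfg$seed, "fusion_init"), {
    if (use_hidden)
      list(W1 = matrix(stats::rnorm(hidden_dim * d, 0, cfg$init_sd),
                       hidden_dim, d),
           b1 = numeric(hidden_dim),
           W2 = matrix(stats::rnorm(hidden_dim, 0, cfg$init_sd), 1, hidden_dim),
           b2 = 0)
    else
      list(W2 = matrix(stats::rnorm(d, 0, cfg$init_sd), 1, d), b2 = 0)
  })
  W_anchor <- NULL
  if (!use_hidden && init_from_heads) {
    # row-major flattening of the (d1+1) x (d2+1) tensor: entry (i, j) sits
    # at (i-1)*(d2+1) + j. Column 1 (j = 1, i > 1) holds z_g; row 1 (i = 1,
    # j > 1) holds z_o. Head weights are rescaled by each standardized
    # feature's sd so the initialized predictor equals w_g.z_g + w_o.z_o.
    d1 <- graph_ckpt$gcn_cfg$out_dim
    d2 <- length(omics_ckpt$head$w)
    col1 <- (seq_len(d1)) * (d2 + 1L) + 1L
    row1 <- 1L + seq_len(d2)
    params$W2[1, col1] <- graph_ckpt$head$w * std$sd[col1]
    params$W2[1, row1] <- omics_ckpt$head$w * std$sd[row1]
    # the ridge shrinks toward this additive single-modal solution rather
    # than toward zero: interactions must earn their way in
    W_anchor <- params$W2
  }

  loss_log <- numeric(cfg$epochs)
  set.seed(derive_seed(cfg$seed, "fusion_sgd"))
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at(cfg, epoch)
    perm <- sample(ids)
    tot_loss <- 0; tot_events <- 0
    for (batch in make_batches(perm, cfg$batch_size)) {
      sb <- surv_of(cohort, batch)
      ne <- sum(sb$event)
      if (ne == 0) next
      Xb <- Xs[match(batch, ids), , drop = FALSE]
      if (use_hidden) {
        pre <- sweep(Xb %*% t(params$W1), 2, params$b1, "+")
        Hh <- tanh(pre)
        theta <- as.vector(Hh %*% t(params$W2)) + params$b2
      } else {
        theta <- as.vector(Xb %*% t(params$W2)) + params$b2
      }
      tot_loss <- tot_loss + cox_pll_loss(theta, sb$time, sb$event)
      tot_events <- tot_events + ne
      gtheta <- cox_pll_grad(theta, sb$time, sb$event) / ne
      if (use_hidden) {
        gW2 <- matrix(crossprod(Hh, gtheta), 1)
        gH <- gtheta %o% as.vector(params$W2)
        gpre <- gH * (1 - Hh^2)
        grads <- list(W1 = crossprod(gpre, Xb), b1 = colSums(gpre),
                      W2 = gW2, b2 = sum(gtheta))
        params <- sgd_update(params, grads, lr, cfg$weight_decay)
      } else {
        grads <- list(W2 = matrix(crossprod(Xb, gtheta), 1), b2 = sum(gtheta))
        if (!is.null(W_anchor))
          grads$W2 <- grads$W2 + cfg$weight_decay * (params$W2 - W_anchor)
        params$W2 <- params$W2 - lr * grads$W2
        if (is.null(W_anchor))
          params$W2 <- params$W2 - lr * cfg$weight_decay * params$W2
        params$b2 <- params$b2 - lr * grads$b2
      }
    }
    loss_log[epoch + 1L] <- if (tot_events > 0) tot_loss / tot_events else NA_real_
  }
  list(stage = "fusion", graph_ckpt = graph_ckpt, omics_ckpt = omics_ckpt,
       params = params, std = std, use_hidden = use_hidden,
       train_cfg = cfg, loss_log = loss_log)
}

fused_design <- function(cohort, graph_ckpt, omics_ckpt, ids) {
  zg <- t(vapply(ids, function(pid)
    embed_graph_patient(graph_ckpt, cohort$graphs[[pid]]),
    numeric(graph_ckpt$gcn_cfg$out_dim)))
  zo <- embed_omics_patients(omics_ckpt, cohort$omics, ids)
  X <- t(vapply(seq_along(ids), function(i)
    flatten_fused(tensor_fuse(zg[i, ], zo[i, ])),
    numeric((ncol(zg) + 1L) * (ncol(zo) + 1L))))
  rownames(X) <- ids
  X
}

# ---- shared prediction and dispatch --------------------------------------

#' Predict per-patient log-hazard scores from a fitted checkpoint
#'
#' @param ckpt A checkpoint from [fit_graph_branch()], [fit_omics_branch()]
#'   or [fit_fusion()].
#' @param cohort The cohort holding the inputs.
#' @param ids Patients to score (default: all the checkpoint's stage can
#'   see).
#' @return Named numeric vector of theta scores (higher = higher hazard).
#' @export
predict_risk <- function(ckpt, cohort, ids = NULL) {
  stage <- ckpt$stage
  if (stage == "graph") {
    if (is.null(ids)) ids <- names(cohort$graphs)
    zg <- t(vapply(ids, function(pid)
      embed_graph_patient(ckpt, cohort$graphs[[pid]]),
      numeric(ckpt$gcn_cfg$out_dim)))
    theta <- as.vector(zg %*% ckpt$head$w + ckpt$head$b)
  } else if (stage == "omics") {
    if (is.null(ids)) ids <- rownames(cohort$omics$expression)
    z <- embed_omics_patients(ckpt, cohort$omics, ids)
    theta <- as.vector(z %*% ckpt$head$w + ckpt$head$b)
  } else if (stage == "fusion") {
    if (is.null(ids))
      ids <- intersect(names(cohort$graphs), rownames(cohort$omics$expression))
    Xs <- apply_standardize(
      fused_design(cohort, ckpt$graph_ckpt, ckpt$omics_ckpt, ids), ckpt$std)
    theta <- if (ckpt$use_hidden) {
      as.vector(tanh(sweep(Xs %*% t(ckpt$params$W1), 2, ckpt$params$b1, "+")) %*%
                  t(ckpt$params$W2)) + ckpt$params$b2
    } else {
      as.vector(Xs %*% t(ckpt$params$W2)) + ckpt$params$b2
    }
  } else stop("unknown checkpoint stage: ", stage)
  stats::setNames(theta, ids)
}

#' Train one stage of the fusion framework
#'
#' Dispatcher over the three training stages. `"graph"` and `"omics"` train
#' the single-modal branches from scratch; `"fusion"` requires both
#' pretrained checkpoints (supplied via `checkpoints`), mirroring the
#' two-stage regime in which the fusion model is initialized from
#' single-modal weights rather than trained end-to-end.
#'
#' @param cohort A cohort object.
#' @param stage `"graph"`, `"omics"` or `"fusion"`.
#' @param model_cfg Stage-specific model config ([gcn_config()] or
#'   [omics_config()]); ignored for fusion.
#' @param train_cfg A [train_config()].
#' @param checkpoints For fusion: `list(graph = ..., omics = ...)`.
#' @param ... Passed to the stage fitter.
#' @return A checkpoint list.
#' @export
train_model <- function(cohort, stage = c("graph", "omics", "fusion"),
                        model_cfg = NULL, train_cfg = train_config(),
                        checkpoints = NULL, ...) {
  stage <- match.arg(stage)
  switch(stage,
    graph = fit_graph_branch(cohort,
                             gcn_cfg = model_cfg %||% gcn_config(),
                             cfg = train_cfg, ...),
    omics = fit_omics_branch(cohort,
                             omics_cfg = model_cfg %||% omics_config(),
                             cfg = train_cfg, ...),
    fusion = {
      if (is.null(checkpoints$graph) || is.null(checkpoints$omics))
        stop("fusion stage requires checkpoints = list(graph = ..., omics = ...)")
      fit_fusion(cohort, checkpoints$graph, checkpoints$omics,
                 cfg = train_cfg, ...)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a checkpoint
#'
#' Checkpoints are named lists keyed by layer name (`W1`, `b1`, ..., `head`,
#' `std`, configs, loss log), serialized with `saveRDS`.
#'
#' @param ckpt Checkpoint list.
#' @param path File path.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
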