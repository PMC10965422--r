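#' Training configuration
#'
#' @param learning_rate Adam learning rate (reference default 1e-6; the
#'   desk-scale synthetic experiments in this package use larger rates,
#'   see the vignette).
#' @param max_steps number of optimisation steps (one sample per step).
#' @param val_every validate (and possibly checkpoint) every this many
#'   steps; validation also runs after the last step.
#' @param seed RNG seed controlling initialisation and sample order.
#' @param checkpoint_criterion \code{"top1_aar"} (higher better,
#'   RMSD tie-break) or \code{"rmsd"} (lower better).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param grad_clip optional global L2 gradient-norm clip; \code{NULL}
#'   disables clipping.
#' @param tau,smoothing,struct_weight loss hyperparameters (see
#'   \code{\link{objectives}}).
#' @return object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-6, max_steps = 1000L,
                         val_every = 100L, seed = 1L,
                         checkpoint_criterion = c("top1_aar", "rmsd"),
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         grad_clip = NULL, tau = 4.2, smoothing = 0.1,
                         struct_weight = 10) {
  stopifnot(learning_rate > 0, max_steps >= 0)
  structure(list(learning_rate = learning_rate,
                 max_steps = as.integer(max_steps),
                 val_every = as.integer(val_every), seed = as.integer(seed),
                 checkpoint_criterion = match.arg(checkpoint_criterion),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 grad_clip = grad_clip, tau = tau, smoothing = smoothing,
                 struct_weight = struct_weight),
            class = "train_config")
}

#' Prepare a (complex, CDR) pair for the model
#'
#' Context selection around the design chain followed by graph
#' encoding; the one preprocessing path used for training, validation
#' and test data alike.
#'
#' @param pair list with elements \code{spec} and \code{complex}.
#' @param config a \code{\link{model_config}}.
#' @param cutoff antigen context distance cutoff in Angstrom.
#' @return a \code{graph_sample} with attribute \code{"cdr_name"}.
#' @export
prepare_sample <- function(pair, config, cutoff = 16) {
  ctx <- select_context(pair$complex, pair$spec$chain_id, cutoff = cutoff)
  s <- encode_sample(ctx, pair$spec, k_neighbors = config$k_neighbors)
  attr(s, "cdr_name") <- pair$spec$cdr_name
  s
}

#' CDR C-alpha RMSD metric
#'
#' Fixed-frame root mean squared deviation over CDR (mask = 1) rows; no
#' superposition is performed because non-CDR coordinates are pinned to
#' the input by the coordinate mask.
#'
#' @param pred_coords,truth_coords L x 3 matrices.
#' @param mask 0/1 CDR mask.
#' @return RMSD in Angstrom.
#' @export
rmsd_metric <- function(pred_coords, truth_coords, mask) {
  rows <- which(mask == 1L)
  if (!length(rows)) stop("RMSD undefined: empty CDR mask")
  dev <- pred_coords[rows, , drop = FALSE] -
    truth_coords[rows, , drop = FALSE]
  sqrt(mean(rowSums(dev * dev)))
}

#' Amino-acid recovery metric
#'
#' Percentage of CDR positions whose true type is among the
#' \code{top_k} most probable predictions; ties are broken by the
#' lower amino-acid index.
#'
#' @param probabilities n x 20 rowwise probability matrix.
#' @param truth_tokens integer truth tokens (1..20).
#' @param top_k 1 (argmax) or 3.
#' @return percent in [0, 100].
#' @export
aar_metric <- function(probabilities, truth_tokens, top_k = 1L) {
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  hits <- aar_hits(probabilities, truth_tokens, top_k)
  100 * mean(hits)
}

aar_hits <- function(probabilities, truth_tokens, top_k) {
  vapply(seq_len(nrow(probabilities)), function(i) {
    top <- order(-probabilities[i, ], seq_len(20L))[seq_len(top_k)]
    truth_tokens[i] %in% top
  }, logical(1))
}

softmax_rows <- function(Z) exp(log_softmax(Z))

# forward one prepared sample and extract predictions on CDR rows
predict_sample <- function(sample, params, config) {
  trace <- egnn_forward(sample, params, config)
  rows <- which(sample$mask == 1L)
  list(pred_coords = trace$per_layer_coords[[config$n_layers]],
       probs = softmax_rows(trace$final_logits[rows, , drop = FALSE]),
       cdr_rows = rows, trace = trace)
}

# pooled metrics over a list of prepared samples
eval_samples <- function(samples, params, config) {
  per <- lapply(samples, function(s) {
    p <- predict_sample(s, params, config)
    list(cdr_name = attr(s, "cdr_name") %||% "CDR",
         rmsd = rmsd_metric(p$pred_coords, s$truth_coords, s$mask),
         hits1 = aar_hits(p$probs, s$truth_tokens[p$cdr_rows], 1L),
         hits3 = aar_hits(p$probs, s$truth_tokens[p$cdr_rows], 3L))
  })
  types <- unique(vapply(per, `[[`, character(1), "cdr_name"))
  do.call(rbind, lapply(types, function(ty) {
    sel <- per[vapply(per, function(z) z$cdr_name == ty, logical(1))]
    data.frame(cdr_name = ty, n = length(sel),
               mean_rmsd = mean(vapply(sel, `[[`, numeric(1), "rmsd")),
               top1_aar = 100 * mean(unlist(lapply(sel, `[[`, "hits1"))),
               top3_aar = 100 * mean(unlist(lapply(sel, `[[`, "hits3"))),
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pooled_criterion <- function(report) {
  w <- report$n * 1
  list(top1 = sum(report$top1_aar * w) / sum(w),
       rmsd = sum(report$mean_rmsd * w) / sum(w))
}

better_checkpoint <- function(cand, best, criterion) {
  if (is.null(best)) return(TRUE)
  if (criterion == "top1_aar") {
    if (cand$top1 != best$top1) return(cand$top1 > best$top1)
    return(cand$rmsd < best$rmsd)
  }
  cand$rmsd < best$rmsd
}

#' Train the co-design model
#'
#' Layer-wise local-loss training: each step runs one prepared sample
#' through the stack, evaluates the full loss breakdown (losses
#' attached to every layer), backpropagates analytically and applies
#' an Adam update. Validation runs every \code{val_every} steps and
#' after the final step; the best checkpoint by the configured
#' criterion is retained alongside the final parameters. Fully
#' deterministic given the seed.
#'
#' @param pairs training pairs from \code{\link{build_pair_dataset}}
#'   (or a list of prepared \code{graph_sample}s).
#' @param config a \code{\link{model_config}}.
#' @param tconfig a \code{\link{train_config}}.
#' @param val_pairs optional validation pairs/samples.
#' @param verbose print progress lines.
#' @return list with \code{params} (best checkpoint), \code{params_final},
#'   \code{config}, \code{history} (per-step loss records) and
#'   \code{val_history}.
#' @export
train <- function(pairs, config, tconfig = train_config(),
                  val_pairs = NULL, verbose = FALSE) {
  stopifnot(length(pairs) > 0)
  as_samples <- function(ps) lapply(ps, function(p)
    if (inherits(p, "graph_sample")) p else prepare_sample(p, config))
  samples <- as_samples(pairs)
  val_samples <- if (!is.null(val_pairs)) as_samples(val_pairs) else NULL

  set.seed(tconfig$seed)
  params <- init_params(config, seed = tconfig$seed)
  theta <- unlist(params, use.names = FALSE)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  history <- vector("list", tconfig$max_steps)
  val_history <- list()
  best <- NULL; best_params <- params

  validate <- function(step) {
    if (is.null(val_samples)) return(invisible(NULL))
    rep <- eval_samples(val_samples, params, config)
    crit <- pooled_criterion(rep)
    val_history[[length(val_history) + 1L]] <<-
      data.frame(step = step, top1_aar = crit$top1, rmsd = crit$rmsd)
    if (better_checkpoint(crit, best, tconfig$checkpoint_criterion)) {
      best <<- crit
      best_params <<- params
    }
    if (verbose)
      message(sprintf("step %d: val top1 %.1f%%, rmsd %.3f",
                      step, crit$top1, crit$rmsd))
  }

  validate(0L)
  if (tconfig$max_steps > 0L) {
    order_idx <- integer(0)
    for (step in seq_len(tconfig$max_steps)) {
      if (!length(order_idx)) order_idx <- sample.int(length(samples))
      i <- order_idx[1]; order_idx <- order_idx[-1]
      lw <- loss_with_grads(samples[[i]], params, config,
                            tau = tconfig$tau,
                            smoothing = tconfig$smoothing,
                            struct_weight = tconfig$struct_weight)
      if (!is.finite(lw$parts$l_total))
        stop("non-finite loss at step ", step, "; aborting (total = ",
             lw$parts$l_total, ")")
      gflat <- unlist(lw$grads, use.names = FALSE)
      if (!is.null(tconfig$grad_clip)) {
        gn <- sqrt(sum(gflat^2))
        if (gn > tconfig$grad_clip) gflat <- gflat * tconfig$grad_clip / gn
      }
      m <- tconfig$beta1 * m + (1 - tconfig$beta1) * gflat
      v <- tconfig$beta2 * v + (1 - tconfig$beta2) * gflat^2
      mhat <- m / (1 - tconfig$beta1^step)
      vhat <- v / (1 - tconfig$beta2^step)
      theta <- theta - tconfig$learning_rate * mhat / (sqrt(vhat) + tconfig$eps)
      params <- utils::relist(theta, params)
      history[[step]] <- data.frame(step = step, sample = i,
                                    l_total = lw$parts$l_total,
                                    l_rmsd = lw$parts$l_rmsd,
                                    l_repulsion = lw$parts$l_repulsion,
                                    l_neighbor = lw$parts$l_neighbor,
                                    l_ce_cdr = lw$parts$l_ce_cdr,
                                    l_ce_noncdr = lw$parts$l_ce_noncdr)
      if (tconfig$val_every > 0L &&
          (step %% tconfig$val_every == 0L || step == tconfig$max_steps))
        validate(step)
    }
  }
  if (is.null(best)) best_params <- params
  list(params = best_params, params_final = params, config = config,
       tconfig = tconfig,
       history = do.call(rbind, history),
       val_history = if (length(val_history))
         do.call(rbind, val_history) else NULL,
       best_val = best)
}

#' Evaluate a trained model on test pairs
#'
#' Per CDR type: mean fixed-frame CDR RMSD over samples, and Top-1 /
#' Top-3 amino-acid recovery pooled over residues (micro-average).
#'
#' @param model list with \code{params} and \code{config} (as returned
#'   by \code{\link{train}}).
#' @param test_pairs pairs or prepared samples, preprocessed
#'   identically to training.
#' @return data.frame with columns \code{cdr_name}, \code{n},
#'   \code{mean_rmsd}, \code{top1_aar}, \code{top3_aar}.
#' @export
evaluate <- function(model, test_pairs) {
  samples <- lapply(test_pairs, function(p)
    if (inherits(p, "graph_sample")) p else prepare_sample(p, model$config))
  rep <- eval_samples(samples, model$params, model$config)
  stopifnot(all(rep$top3_aar >= rep$top1_aar))
  rep
}

#' RMSD of the anchor-line initialisation
#'
#' The straight-line baseline: RMSD between the masked (anchor-line)
#' CDR coordinates a sample starts from and the ground truth. A model
#' that has learned loop geometry must beat this.
#'
#' @param sample a \code{graph_sample}.
#' @return RMSD in Angstrom.
#' @export
baseline_rmsd <- function(sample) {
  rmsd_metric(sample$coords, sample$truth_coords, sample$mask)
}
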