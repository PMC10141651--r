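## Training and inference orchestration: per batch, build clean (and, with
## self-supervision, occluded) inputs, run the dual-branch forward on one
## tape so shared-encoder gradients accumulate from both branches, combine
## the segmentation and similarity losses, and take an Adam step; the
## learning rate follows a stepwise decay schedule.

#' Stepwise learning-rate schedule
#'
#' `initialLr * lrDecay^floor(epoch / decayEvery)` with 0-based epochs, so
#' the first decay applies at epoch `decayEvery`.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a \linkS4class{TrainConfig}.
#' @return learning rate for that epoch.
#' @examples
#' lrSchedule(0, trainConfig())   # 1e-5
#' lrSchedule(5, trainConfig())   # 9e-6
#' @export
lrSchedule <- function(epoch, cfg = trainConfig()) {
  stopifnot(epoch >= 0)
  cfg@initialLr * cfg@lrDecay^(epoch %/% cfg@decayEvery)
}

batch_labels <- function(stacks) {
  d <- dim(labelMap(stacks[[1]]))
  a <- array(0L, c(d[1], d[2], length(stacks)))
  for (i in seq_along(stacks)) a[, , i] <- labelMap(stacks[[i]])
  a
}

#' Train a segmentation network on a slice dataset
#'
#' Runs the joint objective: per batch, the clean inputs (and, when
#' self-supervision is on, per-modality occluded copies through the shared
#' encoders) are forwarded, the decoder consumes the clean branch, and
#' `alpha * Dice + beta * CE + lambdaSim * similarity` is minimised with
#' Adam under the stepwise learning-rate schedule. A non-finite loss aborts
#' with diagnostics.
#'
#' @param dataset list of \linkS4class{ModalityStack} (identical geometry).
#' @param netCfg a \linkS4class{NetworkConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param net optionally, an existing \linkS4class{SegNet} to continue
#'   training; defaults to a fresh build seeded from `trainCfg@seed`.
#' @param verbose print per-epoch loss summaries.
#' @return list of class `segFit` with elements `net`, `history` (per-step
#'   data.frame: epoch, step, lr, seg, sim, total), `epochHistory` (per-epoch
#'   means) and the two configs.
#' @export
trainNetwork <- function(dataset, netCfg, trainCfg = trainConfig(),
                         net = NULL, verbose = FALSE) {
  stopifnot(is(netCfg, "NetworkConfig"), is(trainCfg, "TrainConfig"))
  validObject(trainCfg)
  if (!length(dataset)) stop("empty dataset")
  if (is.null(net)) net <- buildNetwork(netCfg, seed = trainCfg@seed)
  params <- net_param_list(net)
  n_use <- max(1L, round(trainCfg@dataFraction * length(dataset)))
  hist <- list()
  step_t <- 0L
  with_seed(trainCfg@seed, {
    use_idx <- sample(length(dataset))[seq_len(n_use)]
    data <- dataset[use_idx]
    for (epoch in seq_len(trainCfg@epochs) - 1L) {
      lr <- lrSchedule(epoch, trainCfg)
      ord <- sample(length(data))
      starts <- seq(1L, length(data), by = trainCfg@batchSize)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + trainCfg@batchSize - 1L, length(data))]
        stacks <- data[idx]
        labels <- batch_labels(stacks)
        tp <- new_tape(train = TRUE)
        xs_clean <- stack_inputs(net, tp, stacks)
        enc_c <- network_encode(net, tp, xs_clean)
        sim_node <- NULL
        if (trainCfg@selfsup) {
          mask_seed <- trainCfg@seed + 131L * step_t
          masked <- lapply(seq_along(stacks), function(i)
            applyMasks(stacks[[i]], trainCfg@maskStrategy,
                       seed = mask_seed + i - 1L, trainCfg@maskFill)$stack)
          enc_m <- network_encode(net, tp, stack_inputs(net, tp, masked))
          sim_node <- op_similarity(tp, op_concat_c(tp, enc_c$bottleneck),
                                    op_concat_c(tp, enc_m$bottleneck),
                                    eps = trainCfg@epsilon)
        }
        logits <- network_decode(net, tp, enc_c)
        dice_n <- op_dice(tp, op_softmax(tp, logits), labels)
        ce_n <- op_cross_entropy(tp, logits, labels)
        terms <- list(dice_n, ce_n)
        w <- c(trainCfg@alpha, trainCfg@beta)
        if (!is.null(sim_node)) {
          terms <- c(terms, list(sim_node))
          w <- c(w, trainCfg@lambdaSim)
        }
        loss <- op_lincomb(tp, terms, w)
        seg_val <- trainCfg@alpha * dice_n$value + trainCfg@beta * ce_n$value
        sim_val <- if (is.null(sim_node)) 0 else sim_node$value
        if (!is.finite(loss$value))
          stop(sprintf("non-finite loss at epoch %d (seg %.4g, sim %.4g)",
                       epoch, seg_val, sim_val))
        tape_backward(tp, loss)
        step_t <- step_t + 1L
        adam_step(params, lr, step_t)
        hist[[length(hist) + 1L]] <- data.frame(
          epoch = epoch, step = step_t, lr = lr,
          seg = seg_val, sim = sim_val, total = loss$value)
      }
      if (verbose) {
        eh <- do.call(rbind, hist)
        eh <- eh[eh$epoch == epoch, ]
        message(sprintf("epoch %d: seg %.4f sim %.4f (lr %.2g)",
                        epoch, mean(eh$seg), mean(eh$sim), lr))
      }
    }
  })
  history <- do.call(rbind, hist)
  epochHistory <- do.call(rbind, lapply(split(history, history$epoch),
    function(h) data.frame(epoch = h$epoch[1], lr = h$lr[1],
                           seg = mean(h$seg), sim = mean(h$sim),
                           total = mean(h$total))))
  rownames(epochHistory) <- NULL
  structure(list(net = net, history = history, epochHistory = epochHistory,
                 netCfg = netCfg, trainCfg = trainCfg, nUsed = n_use),
            class = "segFit")
}

#' @export
print.segFit <- function(x, ...) {
  cat(sprintf("segFit: %d epochs on %d cases (batch %d)\n",
              x$trainCfg@epochs, x$nUsed, x$trainCfg@batchSize))
  eh <- x$epochHistory
  cat(sprintf("  seg loss %.4f -> %.4f; sim loss %.4f -> %.4f\n",
              eh$seg[1], eh$seg[nrow(eh)], eh$sim[1], eh$sim[nrow(eh)]))
  invisible(x)
}

#' Predict the label map of one case
#'
#' Inference-mode forward pass, per-pixel argmax over class scores, output
#' in the raw BraTS encoding \{0,1,2,4\}. Deterministic.
#'
#' @param net a trained \linkS4class{SegNet} (or a `segFit`).
#' @param stack a \linkS4class{ModalityStack}.
#' @param raw return internal labels \{0,1,2,3\} instead (default FALSE).
#' @return integer matrix of predicted labels.
#' @export
predictCase <- function(net, stack, raw = FALSE) {
  if (inherits(net, "segFit")) net <- net$net
  fw <- networkForward(net, list(stack), train = FALSE)
  lg <- fw$logits[, , , 1, drop = FALSE]
  pred <- apply(lg[, , , 1], c(1, 2), which.max) - 1L
  storage.mode(pred) <- "integer"
  if (raw) pred else bratsLabels(pred)
}

#' Evaluate a network on held-out cases
#'
#' @param net a \linkS4class{SegNet} or `segFit`.
#' @param dataset list of \linkS4class{ModalityStack}.
#' @return list with `perCase` (list of score tables) and `mean` (their
#'   per-region mean).
#' @export
evaluateOnDataset <- function(net, dataset) {
  scores <- lapply(dataset, function(st)
    evaluateSegmentation(predictCase(net, st, raw = TRUE), labelMap(st)))
  list(perCase = scores, mean = meanRegionScores(scores))
}

## ---- checkpointing ---------------------------------------------------------

#' Save network weights and configuration
#'
#' Serialises the configuration, all parameter values and batch-norm running
#' statistics; \code{\link{loadCheckpoint}} rebuilds an identical network.
#'
#' @param net a \linkS4class{SegNet} or `segFit`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
saveCheckpoint <- function(net, path) {
  if (inherits(net, "segFit")) net <- net$net
  params <- net_param_list(net)
  states <- net_state_list(net)
  saveRDS(list(config = net@config,
               values = lapply(params, `[[`, "value"),
               names = vapply(params, `[[`, character(1), "name"),
               running = lapply(states, function(s)
                 list(mean = s$running_mean, var = s$running_var))),
          path)
  invisible(path)
}

#' Load a checkpoint written by \code{\link{saveCheckpoint}}
#'
#' @param path checkpoint file.
#' @return a \linkS4class{SegNet} with restored weights and statistics.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  net <- buildNetwork(ck$config, seed = 0L)
  params <- net_param_list(net)
  if (length(params) != length(ck$values))
    stop("checkpoint incompatible with configuration: ", length(ck$values),
         " stored parameters vs ", length(params), " in the network")
  for (i in seq_along(params)) {
    if (!identical(dim(params[[i]]$value), dim(ck$values[[i]])) &&
        length(params[[i]]$value) != length(ck$values[[i]]))
      stop("checkpoint parameter shape mismatch at ", ck$names[i])
    params[[i]]$value <- ck$values[[i]]
  }
  states <- net_state_list(net)
  for (i in seq_along(states)) {
    states[[i]]$running_mean <- ck$running[[i]]$mean
    states[[i]]$running_var <- ck$running[[i]]$var
  }
  net
}

## All batch-norm state environments of a network, in build order.
net_state_list <- function(net) {
  e <- net@env
  c(do.call(c, lapply(e$encoders, function(enc)
      do.call(c, lapply(enc, `[[`, "states")))),
    do.call(c, lapply(e$aspp, `[[`, "states")),
    e$merge$states,
    if (!is.null(e$hafb)) do.call(c, lapply(e$hafb, `[[`, "states")),
    do.call(c, lapply(e$dec, `[[`, "states")))
}
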