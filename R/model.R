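# User-facing model API: training on labelled site bags, read encoding,
# bag aggregation, stoichiometry estimation and site prediction.

#' Initialize an untrained m6A model
#'
#' @param enc an [encoder_config()].
#' @param heads a [head_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `m6a_model`: list with `params`, `enc`, `heads`,
#'   `seed`, `log` (training history), `stoich_trained` flag.
#' @export
m6a_model <- function(enc = encoder_config(), heads = head_config(),
                      seed = 1L) {
  structure(list(params = init_params(enc, heads, seed), enc = enc,
                 heads = heads, seed = as.integer(seed), log = list(),
                 stoich_trained = FALSE),
            class = "m6a_model")
}

#' @export
print.m6a_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("m6A WaveNet-MIL model: %d parameters, %d-dim ",
                     "embeddings, %d epochs trained%s\n"),
              np, x$enc$embed_dim, length(x$log),
              if (x$stoich_trained) ", stoichiometry head trained" else ""))
  invisible(x)
}

#' Encode read features into embeddings
#'
#' Runs the dilated-convolution encoder on one or more length-1280 read
#' features. Deterministic given the parameters.
#'
#' @param features numeric vector of length 1280, or a reads x 1280 matrix.
#' @param model an `m6a_model`.
#' @return embeddings matrix, reads x embed_dim (a single vector input gives
#'   a 1 x embed_dim matrix).
#' @export
encode_read <- function(features, model) {
  stopifnot(inherits(model, "m6a_model"))
  if (is.vector(features)) features <- matrix(features, nrow = 1L)
  expect_len <- model$enc$input_channels * model$enc$width
  if (ncol(features) != expect_len) {
    stop(sprintf("features must have %d values per read", expect_len),
         call. = FALSE)
  }
  X <- features_to_input(features, model$enc)
  t(encoder_forward(model$params, X, nrow(features), model$enc)$E)
}

#' Aggregate read embeddings into a site-level score
#'
#' @param embeddings reads x embed_dim matrix (from [encode_read()]).
#' @param model an `m6a_model`.
#' @return object of class `site_score`: list with `p_mod` (modification
#'   probability), `p` (the two class probabilities, summing to 1), `C1`
#'   (critical-instance scores), `C2` (bag scores), `C` (their mean),
#'   `attention` (weights, summing to 1), `critical_index`, `bag_embedding`.
#' @export
aggregate_bag <- function(embeddings, model) {
  stopifnot(inherits(model, "m6a_model"), is.matrix(embeddings))
  fw <- dsmil_forward(model$params, t(embeddings))
  structure(list(p_mod = fw$p_mod, p = fw$p, C1 = fw$C1, C2 = fw$C2,
                 C = fw$C, attention = fw$att, critical_index = fw$m,
                 bag_embedding = fw$B),
            class = "site_score")
}

#' Estimate per-site m6A stoichiometry from read embeddings
#'
#' The pseudo-labelling head assigns each read a binary label (argmax of its
#' two-class score); the site's modification ratio is the exact mean of the
#' pseudo-labels.
#'
#' @param embeddings reads x embed_dim matrix.
#' @param model an `m6a_model` (ideally after [train_stoichiometry()]).
#' @return list of class `stoichiometry_estimate`: `pseudo_labels` (0/1 per
#'   read) and `ratio`.
#' @export
estimate_stoichiometry <- function(embeddings, model) {
  stopifnot(inherits(model, "m6a_model"), is.matrix(embeddings),
            nrow(embeddings) >= 1L)
  S <- stoich_forward(model$params, t(embeddings))$S
  labels <- as.integer(S[2L, ] > S[1L, ])
  structure(list(pseudo_labels = labels, ratio = mean(labels)),
            class = "stoichiometry_estimate")
}

bag_loss_grad <- function(model, X, n_reads, label) {
  fwE <- encoder_forward(model$params, X, n_reads, model$enc, keep_cache = TRUE)
  fw <- dsmil_forward(model$params, fwE$E)
  loss <- -log(max(fw$p[label + 1L], 1e-12))
  dC <- fw$p
  dC[label + 1L] <- dC[label + 1L] - 1
  bk <- dsmil_backward(model$params, fwE$E, fw, dC)
  g <- c(bk$grads, encoder_backward(model$params, fwE$cache, bk$dH, model$enc))
  list(loss = loss, grads = g, p_mod = fw$p_mod)
}

# read-level supervised loss: mean cross-entropy of the instance classifier
# over a minibatch of reads, backpropagated through the encoder.
read_batch_loss_grad <- function(model, X, n_reads, labels) {
  fwE <- encoder_forward(model$params, X, n_reads, model$enc, keep_cache = TRUE)
  Si <- model$params$Wi %*% fwE$E + model$params$bi
  mx <- apply(Si, 2L, max)
  P <- exp(sweep(Si, 2L, mx))
  P <- sweep(P, 2L, colSums(P), "/")
  picked <- P[cbind(labels + 1L, seq_len(n_reads))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dS <- P
  dS[cbind(labels + 1L, seq_len(n_reads))] <-
    dS[cbind(labels + 1L, seq_len(n_reads))] - 1
  dS <- dS / n_reads
  g <- list(Wi = dS %*% t(fwE$E), bi = rowSums(dS))
  dE <- t(model$params$Wi) %*% dS
  g <- c(g, encoder_backward(model$params, fwE$cache, dE, model$enc))
  list(loss = loss, grads = g)
}

#' Train the WaveNet-MIL classifier on labelled site bags
#'
#' Two-stage training, matching the data regime of an IVT ground-truth
#' corpus: in-silico mixed sites are assembled from a fully modified and an
#' unmodified run, so the origin (hence the label) of every read is known.
#' Stage 1 pretrains the encoder together with the instance classifier by
#' read-level cross-entropy on all reads carrying labels. Stage 2 trains the
#' MIL aggregator on bag labels over the (by default frozen) read
#' embeddings, one bag per Adam step — the regime the dual-stream
#' aggregator was designed for. If no read labels are available, stage 1 is
#' skipped and the whole model is trained end-to-end on bag labels alone.
#' A fixed seed gives a bit-reproducible run.
#'
#' @param model an `m6a_model`.
#' @param bags list of labelled `site_bag` objects.
#' @param epochs aggregator (stage 2) training epochs.
#' @param pretrain_epochs read-level encoder pretraining epochs (stage 1).
#' @param pretrain_batch reads per stage-1 minibatch.
#' @param freeze_encoder keep encoder weights fixed during stage 2 (default);
#'   `FALSE` fine-tunes the encoder end-to-end through the aggregator.
#' @param lr Adam learning rate (both stages).
#' @param weight_decay decoupled weight decay on the weight matrices.
#' @param seed RNG seed for shuffling.
#' @param log_file optional path: per-epoch JSON-lines training log.
#' @param verbose print per-epoch loss.
#' @return the trained `m6a_model`, with `log` holding per-epoch mean loss
#'   for both stages.
#' @export
train_m6a_model <- function(model, bags, epochs = 20L, pretrain_epochs = 3L,
                            pretrain_batch = 64L, freeze_encoder = TRUE,
                            lr = 1e-3, weight_decay = 1e-3, seed = 1L,
                            log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "m6a_model"), length(bags) >= 1L)
  labels <- vapply(bags, function(b) b$label, integer(1))
  if (anyNA(labels)) stop("all bags must carry a label", call. = FALSE)
  if (!is.null(log_file) && file.exists(log_file)) unlink(log_file)
  log_entry <- function(entry) {
    model$log[[length(model$log) + 1L]] <<- entry
    if (!is.null(log_file)) {
      cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
          file = log_file, append = TRUE, sep = "")
    }
    if (verbose) {
      message(sprintf("%s epoch %d: mean loss %.4f", entry$stage,
                      entry$epoch, entry$mean_loss))
    }
  }

  labelled <- Filter(function(b) !anyNA(b$read_labels), bags)
  with_seed(seed, {
    if (pretrain_epochs > 0L && length(labelled) > 0L) {
      reads <- do.call(rbind, lapply(labelled, `[[`, "features"))
      ry <- unlist(lapply(labelled, `[[`, "read_labels"))
      state <- adam_init(model$params)
      n <- nrow(reads)
      for (ep in seq_len(pretrain_epochs)) {
        ord <- sample(n)
        tot <- 0
        nb <- 0L
        for (start in seq(1L, n, by = pretrain_batch)) {
          idx <- ord[start:min(start + pretrain_batch - 1L, n)]
          X <- features_to_input(reads[idx, , drop = FALSE], model$enc)
          lg <- read_batch_loss_grad(model, X, length(idx), ry[idx])
          st <- adam_step(model$params, lg$grads, state, lr = lr,
                          weight_decay = weight_decay)
          model$params <- st$params
          state <- st$state
          tot <- tot + lg$loss
          nb <- nb + 1L
        }
        log_entry(list(stage = "pretrain", epoch = ep, mean_loss = tot / nb))
      }
    }

    frozen <- freeze_encoder && length(labelled) > 0L && pretrain_epochs > 0L
    inputs <- if (!frozen) {
      lapply(bags, function(b) features_to_input(b$features, model$enc))
    }
    embeds <- if (frozen) {
      lapply(bags, function(b) t(encode_read(b$features, model)))
    }
    nreads <- vapply(bags, function(b) nrow(b$features), integer(1))
    agg_names <- c("Wi", "bi", "Wq", "Wv", "Wb", "bb")
    state <- adam_init(if (frozen) model$params[agg_names] else model$params)
    for (ep in seq_len(epochs)) {
      ord <- sample(length(bags))
      tot <- 0
      for (i in ord) {
        if (frozen) {
          fw <- dsmil_forward(model$params, embeds[[i]])
          loss <- -log(max(fw$p[labels[i] + 1L], 1e-12))
          dC <- fw$p
          dC[labels[i] + 1L] <- dC[labels[i] + 1L] - 1
          g <- dsmil_backward(model$params, embeds[[i]], fw, dC)$grads
          st <- adam_step(model$params[agg_names], g, state, lr = lr,
                          weight_decay = weight_decay)
          model$params[agg_names] <- st$params
        } else {
          lg <- bag_loss_grad(model, inputs[[i]], nreads[i], labels[i])
          loss <- lg$loss
          st <- adam_step(model$params, lg$grads, state, lr = lr,
                          weight_decay = weight_decay)
          model$params <- st$params
        }
        state <- st$state
        tot <- tot + loss
      }
      log_entry(list(stage = "aggregator", epoch = ep,
                     mean_loss = tot / length(bags)))
    }
  })
  model
}

#' Train the stoichiometry (pseudo-labelling) head
#'
#' Fits the fully connected pseudo-labelling head by Adam with cross-entropy
#' on read-level labels over the frozen encoder embeddings. By default all
#' reads with recorded labels are used — in an IVT mixing corpus every
#' read's origin run (modified or not) is known, mixed bags included;
#' `reads = "pure"` restricts to reads from pure 0%/100% bags. Mixed bags
#' are the natural evaluation set either way.
#'
#' @param model a trained `m6a_model`.
#' @param bags list of `site_bag` objects with `read_labels` and `true_ratio`.
#' @param epochs,lr,batch training settings.
#' @param reads `"labelled"` (default: every read with a label) or `"pure"`
#'   (reads from bags whose realized ratio is exactly 0 or 1).
#' @param seed RNG seed.
#' @param verbose print per-epoch loss.
#' @return the model with a fitted stoichiometry head.
#' @export
train_stoichiometry <- function(model, bags, epochs = 30L, lr = 1e-3,
                                batch = 256L, reads = c("labelled", "pure"),
                                seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "m6a_model"))
  reads <- match.arg(reads)
  use <- Filter(function(b) {
    !anyNA(b$read_labels) &&
      (reads == "labelled" || isTRUE(b$true_ratio %in% c(0, 1)))
  }, bags)
  if (length(use) == 0L) {
    stop("no bags with read-level labels available", call. = FALSE)
  }
  H <- do.call(rbind, lapply(use, function(b) encode_read(b$features, model)))
  y <- unlist(lapply(use, function(b) b$read_labels))
  Ht <- t(H)
  n <- ncol(Ht)
  head_names <- c("Sh_W1", "Sh_b1", "Sh_W2", "Sh_b2")
  state <- adam_init(model$params[head_names])
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      tot <- 0
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        fw <- stoich_forward(model$params, Ht[, idx, drop = FALSE])
        mx <- apply(fw$S, 2L, max)
        Pm <- exp(sweep(fw$S, 2L, mx))
        Pm <- sweep(Pm, 2L, colSums(Pm), "/")
        picked <- Pm[cbind(y[idx] + 1L, seq_along(idx))]
        tot <- tot - sum(log(pmax(picked, 1e-12)))
        dS <- Pm
        dS[cbind(y[idx] + 1L, seq_along(idx))] <-
          dS[cbind(y[idx] + 1L, seq_along(idx))] - 1
        dS <- dS / length(idx)
        g <- list()
        g$Sh_W2 <- dS %*% t(fw$H1)
        g$Sh_b2 <- rowSums(dS)
        dH1 <- (t(model$params$Sh_W2) %*% dS) * (fw$H1 > 0)
        g$Sh_W1 <- dH1 %*% t(Ht[, idx, drop = FALSE])
        g$Sh_b1 <- rowSums(dH1)
        st <- adam_step(model$params[head_names], g, state, lr = lr)
        model$params[head_names] <- st$params
        state <- st$state
      }
      if (verbose) message(sprintf("stoich epoch %d: mean loss %.4f", ep, tot / n))
    }
  })
  model$stoich_trained <- TRUE
  model
}

#' Predict m6A status for a set of site bags
#'
#' @param model a trained `m6a_model`.
#' @param bags list of `site_bag` objects.
#' @param threshold call threshold on P(mod); `>=` is inclusive. Default 0.5;
#'   use 0.9 for high-confidence calls.
#' @return data.frame of class `site_calls`: `transcript`, `pos` (1-based
#'   central A), `motif`, `coverage`, `p_mod`, `call` (0/1), `mod_ratio`.
#' @export
predict_sites <- function(model, bags, threshold = 0.5) {
  stopifnot(inherits(model, "m6a_model"))
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  rows <- lapply(bags, function(b) {
    H <- encode_read(b$features, model)
    sc <- aggregate_bag(H, model)
    st <- estimate_stoichiometry(H, model)
    data.frame(transcript = b$transcript, pos = b$pos + 1L, motif = b$motif,
               coverage = nrow(b$features), p_mod = sc$p_mod,
               call = as.integer(sc$p_mod >= threshold),
               mod_ratio = st$ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("site_calls", "data.frame")
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: parameters plus both configs, the
#' initialization seed and the training log.
#' @param model an `m6a_model`.
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "m6a_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), !is.null(obj$params), !is.null(obj$enc))
  structure(obj, class = "m6a_model")
}
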