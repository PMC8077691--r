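# GRU encoder-decoder translator with additive (Bahdanau) attention.
# Forward pass, backpropagation through time and Adam are implemented
# with plain matrix algebra; all randomness derives from the config seed.

#' Translator model configuration
#'
#' Defaults follow the reference training setup: Adam at learning rate
#' 0.0005, batches of 256 sequences, source/target content lengths 48
#' and 78 (two positions are added internally for the start/end
#' markers), embeddings of 256 and 512 recurrent units.
#'
#' @param source_vocab_size,target_vocab_size vocabulary sizes (filled
#'   in automatically by [train_translator()] when NULL).
#' @param embedding_dim embedding dimension.
#' @param recurrent_units GRU state size (also the attention width).
#' @param learning_rate Adam step size.
#' @param batch_size sequences per gradient step.
#' @param max_source_len,max_target_len content token limits.
#' @param epochs training epochs.
#' @param seed integer seed for initialization and shuffling.
#' @return a `model_config` list.
#' @export
model_config <- function(source_vocab_size = NULL, target_vocab_size = NULL,
                         embedding_dim = 256L, recurrent_units = 512L,
                         learning_rate = 5e-4, batch_size = 256L,
                         max_source_len = 48L, max_target_len = 78L,
                         epochs = 10L, seed = 1L) {
  cfg <- list(source_vocab_size = source_vocab_size,
              target_vocab_size = target_vocab_size,
              embedding_dim = as.integer(embedding_dim),
              recurrent_units = as.integer(recurrent_units),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_source_len = as.integer(max_source_len),
              max_target_len = as.integer(max_target_len),
              epochs = as.integer(epochs), seed = as.integer(seed))
  stopifnot(cfg$embedding_dim > 0, cfg$recurrent_units > 0,
            cfg$learning_rate > 0, cfg$batch_size > 0, cfg$epochs >= 0)
  structure(cfg, class = "model_config")
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Parameter bundle; vocab sizes must be set in the config.
.init_params <- function(cfg) {
  e <- cfg$embedding_dim; h <- cfg$recurrent_units
  vs <- cfg$source_vocab_size; vt <- cfg$target_vocab_size
  list(
    src_emb = .glorot(vs, e), tgt_emb = .glorot(vt, e),
    enc_W = .glorot(e, 3 * h), enc_U = .glorot(h, 3 * h),
    enc_b = rep(0, 3 * h),
    dec_W = .glorot(e + h, 3 * h), dec_U = .glorot(h, 3 * h),
    dec_b = rep(0, 3 * h),
    att_W1 = .glorot(h, h), att_W2 = .glorot(h, h),
    att_v = stats::runif(h, -sqrt(6 / (h + 1)), sqrt(6 / (h + 1))),
    out_W = .glorot(h, vt), out_b = rep(0, vt)
  )
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# One GRU step for a batch. X [B,d], H [B,h]. Returns new state + cache.
.gru_forward <- function(X, H, W, U, b) {
  h <- ncol(H)
  zi <- 1:h; ri <- (h + 1):(2 * h); ni <- (2 * h + 1):(3 * h)
  G <- X %*% W
  G <- sweep(G, 2, b, "+")
  Gh <- H %*% U
  z <- .sigmoid(G[, zi, drop = FALSE] + Gh[, zi, drop = FALSE])
  r <- .sigmoid(G[, ri, drop = FALSE] + Gh[, ri, drop = FALSE])
  uhn <- Gh[, ni, drop = FALSE]
  nn <- tanh(G[, ni, drop = FALSE] + r * uhn)
  H2 <- z * H + (1 - z) * nn
  list(H = H2, cache = list(X = X, Hprev = H, z = z, r = r, nn = nn,
                            uhn = uhn))
}

# Backward through one GRU step. Returns dX, dHprev and increments the
# supplied gradient accumulators (environments keyed by name).
.gru_backward <- function(dH2, cache, W, U, grads, wname, uname, bname) {
  z <- cache$z; r <- cache$r; nn <- cache$nn
  H <- cache$Hprev; X <- cache$X; uhn <- cache$uhn
  h <- ncol(z)
  dz <- dH2 * (H - nn)
  dnn <- dH2 * (1 - z)
  dH <- dH2 * z
  da_n <- dnn * (1 - nn^2)
  dr <- da_n * uhn
  da_r <- dr * r * (1 - r)
  da_z <- dz * z * (1 - z)
  dG <- cbind(da_z, da_r, da_n)
  dGh <- cbind(da_z, da_r, da_n * r)
  grads[[wname]] <- grads[[wname]] + crossprod(X, dG)
  grads[[uname]] <- grads[[uname]] + crossprod(H, dGh)
  grads[[bname]] <- grads[[bname]] + colSums(dG)
  list(dX = dG %*% t(W), dH = dH + dGh %*% t(U))
}

#' Additive attention over encoder outputs
#'
#' Scores `v . tanh(W1 enc_t + W2 dec)` are softmax-normalized into
#' weights; the context vector is the weight-averaged encoder output.
#'
#' @param decoder_state numeric vector (length = recurrent units).
#' @param encoder_outputs matrix, one row per source position.
#' @param params list with `W1`, `W2`, `v` (a trained model's attention
#'   parameters; [translator_attention_params()] extracts them).
#' @return list with `context` (vector) and `weights` (vector over
#'   source positions; nonnegative, sums to 1).
#' @export
attend <- function(decoder_state, encoder_outputs, params) {
  if (is.vector(encoder_outputs)) {
    encoder_outputs <- matrix(encoder_outputs, nrow = 1)
  }
  if (ncol(encoder_outputs) != length(decoder_state)) {
    stop("dimension mismatch between decoder state and encoder outputs")
  }
  pre <- tanh(encoder_outputs %*% params$W1 +
                matrix(decoder_state %*% params$W2,
                       nrow(encoder_outputs), length(params$v), byrow = TRUE))
  scores <- as.numeric(pre %*% params$v)
  scores <- scores - max(scores)
  w <- exp(scores) / sum(exp(scores))
  list(context = as.numeric(crossprod(encoder_outputs, w)), weights = w)
}

#' Attention parameters of a trained translator
#' @param model a `translator_model`.
#' @return list with `W1`, `W2`, `v`.
#' @export
translator_attention_params <- function(model) {
  list(W1 = model$params$att_W1, W2 = model$params$att_W2,
       v = model$params$att_v)
}

#' Padding-masked mean cross-entropy
#'
#' Mean over positions whose target index is not the pad index (0) of
#' `-log p(target)`; pad positions contribute nothing. An all-pad
#' target yields 0 with a warning. Zero probabilities are clamped.
#'
#' @param target_indices integer vector of gold indices (0 = pad).
#' @param predicted matrix of predicted distributions, one row per
#'   position (columns = vocabulary indices 0, 1, ...).
#' @return the masked mean loss (scalar).
#' @export
masked_loss <- function(target_indices, predicted) {
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1)
  stopifnot(length(target_indices) == nrow(predicted))
  keep <- target_indices != 0L
  if (!any(keep)) {
    warning("all-pad target: loss defined as 0")
    return(0)
  }
  p <- predicted[cbind(which(keep), target_indices[keep] + 1L)]
  p <- pmax(p, 1e-12)
  mean(-log(p))
}

# Row-softmax with -Inf masking support.
.softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Full forward + backward pass over one batch. Xs, Yt are [B, L]
# integer matrices of vocabulary indices (0 = pad). Returns loss and
# gradients (list matching params).
.batch_grads <- function(params, cfg, Xs, Yt) {
  B <- nrow(Xs); Ls <- ncol(Xs); Lt <- ncol(Yt)
  h <- cfg$recurrent_units
  # ---- encoder forward ----
  H <- matrix(0, B, h)
  enc_cache <- vector("list", Ls)
  encH <- vector("list", Ls)
  for (s in seq_len(Ls)) {
    X <- params$src_emb[Xs[, s] + 1L, , drop = FALSE]
    st <- .gru_forward(X, H, params$enc_W, params$enc_U, params$enc_b)
    H <- st$H
    enc_cache[[s]] <- st$cache
    encH[[s]] <- H
  }
  # decoder starts from each sequence's true final encoder state (pad
  # steps are ignored, matching inference, where pads are stripped)
  src_len <- rowSums(Xs != 0L)
  enc_final <- matrix(0, B, h)
  for (b in seq_len(B)) enc_final[b, ] <- encH[[src_len[b]]][b, ]
  src_pad <- Xs == 0L  # [B, Ls]
  EW1 <- lapply(encH, function(E) E %*% params$att_W1)

  # ---- decoder forward (teacher forcing) ----
  dec_cache <- vector("list", Lt - 1L)
  H <- enc_final
  total_loss <- 0
  n_tok <- sum(Yt[, -1L, drop = FALSE] != 0L)
  dlogits_list <- vector("list", Lt - 1L)
  for (t in seq_len(Lt - 1L)) {
    q <- H
    qW2 <- q %*% params$att_W2
    S <- matrix(0, B, Ls)
    for (s in seq_len(Ls)) {
      S[, s] <- tanh(EW1[[s]] + qW2) %*% params$att_v
    }
    S[src_pad] <- -Inf
    w <- .softmax_rows(S)
    ctx <- matrix(0, B, h)
    for (s in seq_len(Ls)) ctx <- ctx + w[, s] * encH[[s]]
    emb <- params$tgt_emb[Yt[, t] + 1L, , drop = FALSE]
    X <- cbind(emb, ctx)
    st <- .gru_forward(X, H, params$dec_W, params$dec_U, params$dec_b)
    H <- st$H
    logits <- H %*% params$out_W
    logits <- sweep(logits, 2, params$out_b, "+")
    P <- .softmax_rows(logits)
    tgt <- Yt[, t + 1L]
    keep <- tgt != 0L
    if (any(keep)) {
      pk <- pmax(P[cbind(which(keep), tgt[keep] + 1L)], 1e-12)
      total_loss <- total_loss + sum(-log(pk))
    }
    dlog <- P
    dlog[cbind(seq_len(B), tgt + 1L)] <- dlog[cbind(seq_len(B), tgt + 1L)] - 1
    dlog[!keep, ] <- 0
    dlogits_list[[t]] <- dlog / n_tok
    dec_cache[[t]] <- list(q = q, qW2 = qW2, w = w, gru = st$cache,
                           Hout = H)
  }
  loss <- total_loss / n_tok

  # ---- backward ----
  grads <- new.env(parent = emptyenv())
  for (nm in names(params)) grads[[nm]] <- params[[nm]] * 0
  dencH <- lapply(seq_len(Ls), function(s) matrix(0, B, h))
  e <- cfg$embedding_dim
  dH <- matrix(0, B, h)
  for (t in rev(seq_len(Lt - 1L))) {
    cc <- dec_cache[[t]]
    dlog <- dlogits_list[[t]]
    grads$out_W <- grads$out_W + crossprod(cc$Hout, dlog)
    grads$out_b <- grads$out_b + colSums(dlog)
    dH <- dH + dlog %*% t(params$out_W)
    bk <- .gru_backward(dH, cc$gru, params$dec_W, params$dec_U, grads,
                        "dec_W", "dec_U", "dec_b")
    dX <- bk$dX
    demb <- dX[, seq_len(e), drop = FALSE]
    dctx <- dX[, e + seq_len(h), drop = FALSE]
    idx <- Yt[, t] + 1L
    for (b in seq_len(B)) {
      grads$tgt_emb[idx[b], ] <- grads$tgt_emb[idx[b], ] + demb[b, ]
    }
    # attention backward
    w <- cc$w
    dW <- matrix(0, B, Ls)
    for (s in seq_len(Ls)) {
      dW[, s] <- rowSums(dctx * encH[[s]])
      dencH[[s]] <- dencH[[s]] + w[, s] * dctx
    }
    dS <- w * (dW - rowSums(w * dW))
    dqW2 <- matrix(0, B, h)
    for (s in seq_len(Ls)) {
      Ts <- tanh(EW1[[s]] + cc$qW2)
      dT <- dS[, s] %o% params$att_v
      dpre <- dT * (1 - Ts^2)
      grads$att_v <- grads$att_v + as.numeric(crossprod(Ts, dS[, s]))
      grads$att_W1 <- grads$att_W1 + crossprod(encH[[s]], dpre)
      dencH[[s]] <- dencH[[s]] + dpre %*% t(params$att_W1)
      dqW2 <- dqW2 + dpre
    }
    grads$att_W2 <- grads$att_W2 + crossprod(cc$q, dqW2)
    dq <- dqW2 %*% t(params$att_W2)
    dH <- bk$dH + dq  # gradient on the previous decoder state
  }
  # decoder initial state = per-sequence final encoder state: route its
  # gradient to each row's last real source step
  dHenc <- matrix(0, B, h)
  for (s in rev(seq_len(Ls))) {
    at_end <- src_len == s
    if (any(at_end)) dHenc[at_end, ] <- dHenc[at_end, ] + dH[at_end, ]
    dHenc <- dHenc + dencH[[s]]
    bk <- .gru_backward(dHenc, enc_cache[[s]], params$enc_W, params$enc_U,
                        grads, "enc_W", "enc_U", "enc_b")
    idx <- Xs[, s] + 1L
    for (b in seq_len(B)) {
      grads$src_emb[idx[b], ] <- grads$src_emb[idx[b], ] + bk$dX[b, ]
    }
    dHenc <- bk$dH
  }
  g <- as.list(grads)
  list(loss = loss, grads = g[names(params)])
}

# ---- training -------------------------------------------------------------

#' Train the attention translator on a pair dataset
#'
#' Teacher-forced training (the decoder always sees the gold previous
#' token, starting from the start marker) with padding-masked mean
#' cross-entropy and Adam. Vocabularies are built from the training
#' corpus; sequences are encoded to `content + 2` positions. All
#' randomness (initialization, shuffling) derives from `config$seed`,
#' so identical inputs reproduce identical loss traces.
#'
#' @param dataset a `pair_dataset` (see [build_pair_dataset()]).
#' @param config a [model_config()].
#' @param checkpoint_dir optional directory; when given, parameters are
#'   saved after every epoch.
#' @param min_count rare-token cutoff for both vocabularies.
#' @param verbose print the per-epoch loss.
#' @return a `translator_model` with elements `params`, `config`,
#'   `src_vocab`, `tgt_vocab` and `loss_trace` (mean loss per epoch).
#' @export
train_translator <- function(dataset, config, checkpoint_dir = NULL,
                             min_count = 1L, verbose = FALSE) {
  stopifnot(inherits(dataset, "pair_dataset"),
            inherits(config, "model_config"))
  recs <- dataset$records
  if (nrow(recs) == 0) stop("cannot train on an empty dataset")
  src_vocab <- build_vocabulary(recs$source_tokens, min_count)
  tgt_vocab <- build_vocabulary(recs$target_tokens, min_count)
  config$source_vocab_size <- vocab_size(src_vocab)
  config$target_vocab_size <- vocab_size(tgt_vocab)
  Ls <- max(lengths(recs$source_tokens)) + 2L
  Lt <- max(lengths(recs$target_tokens)) + 2L
  Xs <- t(vapply(recs$source_tokens, encode_sequence, integer(Ls),
                 vocab = src_vocab, padded_length = Ls))
  Yt <- t(vapply(recs$target_tokens, encode_sequence, integer(Lt),
                 vocab = tgt_vocab, padded_length = Lt))

  set.seed(config$seed)
  params <- .init_params(config)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(Xs)
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0; ep_tok <- 0
    for (st in starts) {
      take <- ord[st:min(st + config$batch_size - 1L, n)]
      out <- .batch_grads(params, config,
                          Xs[take, , drop = FALSE], Yt[take, , drop = FALSE])
      step <- step + 1L
      lr_t <- config$learning_rate *
        sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(params)) {
        g <- out$grads[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
        params[[nm]] <- params[[nm]] - lr_t * m[[nm]] / (sqrt(v[[nm]]) + eps)
      }
      ntk <- sum(Yt[take, -1L, drop = FALSE] != 0L)
      ep_loss <- ep_loss + out$loss * ntk
      ep_tok <- ep_tok + ntk
    }
    trace[ep] <- ep_loss / ep_tok
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, trace[ep]))
    if (!is.null(checkpoint_dir)) {
      model <- structure(list(params = params, config = config,
                              src_vocab = src_vocab, tgt_vocab = tgt_vocab,
                              loss_trace = trace[seq_len(ep)]),
                         class = "translator_model")
      save_translator(model, checkpoint_dir)
    }
  }
  structure(list(params = params, config = config,
                 src_vocab = src_vocab, tgt_vocab = tgt_vocab,
                 loss_trace = trace),
            class = "translator_model")
}

#' @export
print.translator_model <- function(x, ...) {
  cat(sprintf(
    "<translator_model> %d->%d tokens, emb %d, units %d, %d epochs (final loss %.4f)\n",
    x$config$source_vocab_size, x$config$target_vocab_size,
    x$config$embedding_dim, x$config$recurrent_units,
    length(x$loss_trace),
    if (length(x$loss_trace)) utils::tail(x$loss_trace, 1) else NA))
  invisible(x)
}

#' Greedy decoding of one source sequence
#'
#' Feeds the argmax token back as the next decoder input, stopping at
#' the end marker or the target length bound.
#'
#' @param model a `translator_model`.
#' @param source integer vector of source vocabulary indices, a
#'   `token_sequence`, or a character vector of source tokens.
#' @return a `token_sequence` of content tokens (no start/end markers).
#' @export
greedy_translate <- function(model, source) {
  cfg <- model$config
  if (inherits(source, "token_sequence")) source <- source$tokens
  if (is.character(source)) {
    source <- encode_sequence(source, model$src_vocab,
                              length(source) + 2L)
  }
  params <- model$params
  h <- cfg$recurrent_units
  keep <- source != 0L
  src <- source[keep]
  H <- matrix(0, 1, h)
  encH <- matrix(0, length(src), h)
  for (s in seq_along(src)) {
    X <- params$src_emb[src[s] + 1L, , drop = FALSE]
    H <- .gru_forward(X, H, params$enc_W, params$enc_U, params$enc_b)$H
    encH[s, ] <- H
  }
  att <- translator_attention_params(model)
  out <- integer(0)
  tok <- model$tgt_vocab$start
  max_steps <- cfg$max_target_len
  for (t in seq_len(max_steps + 1L)) {
    a <- attend(as.numeric(H), encH, att)
    emb <- params$tgt_emb[tok + 1L, , drop = FALSE]
    X <- cbind(emb, matrix(a$context, 1))
    H <- .gru_forward(X, H, params$dec_W, params$dec_U, params$dec_b)$H
    logits <- as.numeric(H %*% params$out_W) + params$out_b
    tok <- which.max(logits) - 1L
    if (tok == model$tgt_vocab$end) break
    out <- c(out, tok)
    if (length(out) >= max_steps) break
  }
  .token_sequence(model$tgt_vocab$index_to_token[out + 1L])
}

#' Translate a character column of sources through a model
#'
#' Tibble-first convenience: tokenizes each source string with the
#' tokenizer matching `source_side`, translates greedily and returns
#' detokenized predictions.
#'
#' @param model a `translator_model`.
#' @param data tibble with a `source` column (or a character vector).
#' @param source_side `"selfies"` or `"name"`.
#' @return tibble with columns `source` and `prediction`.
#' @export
translate_strings <- function(model, data, source_side = c("selfies", "name")) {
  source_side <- match.arg(source_side)
  src <- if (is.character(data)) data else data$source
  preds <- vapply(src, function(x) {
    toks <- if (source_side == "selfies") tokenize_selfies(x) else
      tokenize_iupac(x)
    out <- tryCatch(greedy_translate(model, toks),
                    error = function(e) .token_sequence(character(0)))
    detokenize(out)
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(source = src, prediction = preds)
}

#' Save a translator checkpoint directory
#'
#' Writes parameters (RDS), the config and both vocabularies (JSON).
#'
#' @param model a `translator_model`.
#' @param dir checkpoint directory (created if missing).
#' @return the directory, invisibly.
#' @export
save_translator <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  saveRDS(model$loss_trace, file.path(dir, "loss_trace.rds"))
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  write_vocabulary(model$src_vocab, file.path(dir, "src_vocab.json"))
  write_vocabulary(model$tgt_vocab, file.path(dir, "tgt_vocab.json"))
  invisible(dir)
}

#' Load a translator checkpoint directory
#'
#' @param dir directory written by [save_translator()].
#' @return a `translator_model`.
#' @export
load_translator <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"))
  cfg <- model_config(
    source_vocab_size = cfgl$source_vocab_size,
    target_vocab_size = cfgl$target_vocab_size,
    embedding_dim = cfgl$embedding_dim,
    recurrent_units = cfgl$recurrent_units,
    learning_rate = cfgl$learning_rate, batch_size = cfgl$batch_size,
    max_source_len = cfgl$max_source_len,
    max_target_len = cfgl$max_target_len,
    epochs = cfgl$epochs, seed = cfgl$seed
  )
  structure(list(params = readRDS(file.path(dir, "params.rds")),
                 config = cfg,
                 src_vocab = read_vocabulary(file.path(dir, "src_vocab.json")),
                 tgt_vocab = read_vocabulary(file.path(dir, "tgt_vocab.json")),
                 loss_trace = readRDS(file.path(dir, "loss_trace.rds"))),
            class = "translator_model")
}
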