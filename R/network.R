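#' Build the columnar Timer/Inhibitory/Messenger network
#'
#' Constructs the weight matrix, population labels and plastic-synapse
#' bookkeeping for \code{n_columns} functional columns.  Each column holds
#' \code{neurons_per_column} cells split into Timer (T), Timer-associated
#' inhibitory (I_T), Messenger (M) and Messenger-associated inhibitory (I_M)
#' populations.  Within a column, T cells connect recurrently onto T and
#' drive I_T and M; I_T inhibits T and M; M recruits I_M, which inhibits T
#' and M (terminating the column's activity after the Messenger burst); M
#' cells project to the next column's T cells.  I_M cells also send weak
#' lateral inhibitory projections to the T cells of neighbouring columns.
#' The T->T recurrent, T->M, and M->next-column-T classes are plastic and
#' initialized with small non-zero random weights; all other classes are
#' static at their configured values.  All weights are non-negative: the
#' valence of a connection is carried by the presynaptic cell's reversal
#' potential, not by the weight sign.
#'
#' @param n_columns number of columns (>= 1).
#' @param config model configuration from \code{\link{default_config}}.
#' @param seed integer seed for the initial plastic weights.
#' @return an object of class \code{timer_network} with elements \code{W}
#'   (dense weight matrix, entry \code{W[post, pre]}), \code{Win}
#'   (feed-forward input weights), \code{labels} (per-neuron column and cell
#'   class), \code{plastic} (data frame of plastic synapses), and the
#'   configuration used.
#' @export
#' @examples
#' net <- build_network(1, default_config(), seed = 1)
#' nrow(net$labels)  # 400 neurons in a single column
build_network <- function(n_columns, config = default_config(), seed = 1L) {
  if (n_columns < 1) stop("n_columns must be >= 1")
  validate_config(config)
  a <- config$architecture
  npc <- a$neurons_per_column
  n <- n_columns * npc

  cls_col <- c(rep("T", a$n_T), rep("IT", a$n_IT),
               rep("M", a$n_M), rep("IM", a$n_IM))
  labels <- data.frame(
    neuron = seq_len(n),
    column = rep(seq_len(n_columns), each = npc),
    class = rep(cls_col, n_columns),
    stringsAsFactors = FALSE
  )
  # synaptic activation class of each presynaptic neuron: 0 T, 1 I, 2 M
  sclass <- integer(n)
  sclass[labels$class == "T"] <- 0L
  sclass[labels$class %in% c("IT", "IM")] <- 1L
  sclass[labels$class == "M"] <- 2L

  idx <- function(col, cl) labels$neuron[labels$column == col &
                                           labels$class == cl]

  W <- matrix(0, n, n)
  W_slow <- matrix(0, n, n)
  W_gate <- matrix(0, n, n)
  plast_pre <- integer(0); plast_post <- integer(0); plast_cls <- character(0)
  V_th_i <- numeric(n)

  with_seed(seed, {
    # heterogeneous excitability: per-neuron thresholds spread uniformly,
    # giving the population a graded recruitment curve (smooth rate decay
    # instead of an all-or-none cliff); kept above the refractory hold
    # per-neuron threshold heterogeneity (graded population recruitment);
    # the spread and the mean offset are adjustable per population, e.g. a
    # raised, narrow I_T threshold makes the Messenger gate release sharply
    # while Timer activity is still substantial
    spread <- rep(config$neuron$V_th_spread %||% 0, n)
    spread_cls <- config$architecture$V_th_spread_class
    if (!is.null(spread_cls))
      for (cl in names(spread_cls))
        spread[labels$class == cl] <- spread_cls[[cl]]
    V_th_i <- config$neuron$V_th + runif(n, -0.5, 0.5) * spread
    off <- config$architecture$V_th_offset
    if (!is.null(off))
      for (cl in names(off))
        V_th_i[labels$class == cl] <- V_th_i[labels$class == cl] +
          off[[cl]]
    V_th_i <- pmax(V_th_i, config$neuron$V_hold + 0.5)
    for (col in seq_len(n_columns)) {
      iT <- idx(col, "T"); iIT <- idx(col, "IT")
      iM <- idx(col, "M"); iIM <- idx(col, "IM")

      # static intra-column classes
      W[iT, iIT] <- a$w_IT_T
      W[iM, iIT] <- a$w_IT_M
      W[iIM, iM] <- a$w_M_IM
      W[iT, iIM] <- a$w_IM_T
      W[iM, iIM] <- a$w_IM_M
      # mutual inhibition within I_M: common-mode drive (e.g. an injected
      # current shared by the population) is normalized away, keeping the
      # ramp's recruitment point stable
      if (!is.null(a$w_IM_IM) && a$w_IM_IM > 0) {
        W[iIM, iIM] <- a$w_IM_IM
        W[cbind(iIM, iIM)] <- 0
      }
      if (a$w_T_M > 0) W[iM, iT] <- a$w_T_M
      # slowly integrating T -> I_M drive: the Messenger-associated
      # inhibitory subset accumulates evidence of ongoing Timer activity
      # and ramps up, giving the Timer population its graded decay
      W_slow[iIM, iT] <- a$w_T_IM_slow
      # the Messenger burst charges a slow drive onto I_M, so the quench
      # outlasts the fading input trace and the column stays terminated
      W_slow[iIM, iM] <- a$w_M_IM_slow %||% 0
      # fast (AMPA-like) T -> I_T drive: the gate population reads the
      # instantaneous Timer rate, so its cut-out tracks the Timer's decline
      # instead of the saturating slow activation
      W_gate[iIT, iT] <- a$w_T_IT

      # plastic T->T recurrent (no autapses)
      g <- expand.grid(post = iT, pre = iT)
      g <- g[g$post != g$pre, ]
      w0 <- a$w_TT_init * runif(nrow(g), 0.5, 1.5)
      W[cbind(g$post, g$pre)] <- w0
      plast_pre <- c(plast_pre, g$pre)
      plast_post <- c(plast_post, g$post)
      plast_cls <- c(plast_cls, rep("TT", nrow(g)))

      # plastic T->M intra-column
      g <- expand.grid(post = iM, pre = iT)
      W[cbind(g$post, g$pre)] <- W[cbind(g$post, g$pre)] +
        a$w_TM_init * runif(nrow(g), 0.5, 1.5)
      plast_pre <- c(plast_pre, g$pre)
      plast_post <- c(plast_post, g$post)
      plast_cls <- c(plast_cls, rep("TM", nrow(g)))

      # plastic M -> next-column T feed-forward
      if (col < n_columns) {
        # launches must also close the next column's Messenger gate the way
        # external input does: static M -> next-column I_T drive
        W[idx(col + 1, "IT"), iM] <- a$w_M_IT_next %||% 0
        iTn <- idx(col + 1, "T")
        g <- expand.grid(post = iTn, pre = iM)
        W[cbind(g$post, g$pre)] <- a$w_MT_init * runif(nrow(g), 0.5, 1.5)
        plast_pre <- c(plast_pre, g$pre)
        plast_post <- c(plast_post, g$post)
        plast_cls <- c(plast_cls, rep("MT", nrow(g)))
      }

      # static lateral inhibition onto neighbouring columns' T cells
      for (nb in c(col - 1, col + 1)) {
        if (nb >= 1 && nb <= n_columns && a$w_lateral_I > 0)
          W[idx(nb, "T"), iIM] <- W[idx(nb, "T"), iIM] + a$w_lateral_I
      }
    }
  })

  # feed-forward input channels, one block per column, targeting T and I_T
  inp <- config$input
  n_ch <- inp$n_channels * n_columns
  Win <- matrix(0, n, n_ch)
  channel_column <- rep(seq_len(n_columns), each = inp$n_channels)
  for (col in seq_len(n_columns)) {
    ch <- which(channel_column == col)
    Win[idx(col, "T"), ch] <- inp$w_input_T
    Win[idx(col, "IT"), ch] <- inp$w_input_IT
  }

  # the ignition (external pulse or learned launch) drives a saturating
  # slow envelope trace on the Timer cells; because the trace saturates,
  # the timing envelope is stereotyped regardless of how the column was
  # ignited, and its fading is what the recurrent weights amplify
  is_T <- labels$class == "T"
  Yin <- matrix(0, n, n_ch)
  for (col in seq_len(n_columns))
    Yin[is_T & labels$column == col, channel_column == col] <-
      inp$rho_y
  Y_launch <- matrix(0, n, n)   # filled from the learned M->T weights
  G_slow <- ifelse(is_T, inp$g_envelope, 0)

  net <- list(
    W = W, W_slow = W_slow, W_gate = W_gate, Win = Win,
    Yin = Yin, Y_launch = Y_launch, G_slow = G_slow,
    labels = labels, sclass = sclass,
    V_th = V_th_i,
    channel_column = channel_column,
    plastic = data.frame(pre = plast_pre, post = plast_post,
                         class = plast_cls, stringsAsFactors = FALSE),
    n_columns = n_columns, config = config, seed = seed, trained = FALSE
  )
  class(net) <- "timer_network"
  net
}

#' @export
print.timer_network <- function(x, ...) {
  cat("<timer_network> ", x$n_columns, " column(s), ",
      nrow(x$labels), " neurons, ",
      nrow(x$plastic), " plastic synapses",
      if (x$trained) ", trained" else ", naive", "\n", sep = "")
  for (cl in unique(x$plastic$class)) {
    cat(sprintf("  mean %-2s weight: %.3e\n", cl, weight_class_mean(x, cl)))
  }
  invisible(x)
}

#' Mean weight of one plastic connection class
#'
#' @param net a \code{timer_network}.
#' @param class one of \code{"TT"}, \code{"TM"}, \code{"MT"}.
#' @return mean synaptic weight of the class.
#' @export
weight_class_mean <- function(net, class = "TT") {
  k <- net$plastic$class == class
  if (!any(k)) stop("no plastic synapses of class ", class)
  mean(net$W[cbind(net$plastic$post[k], net$plastic$pre[k])])
}

#' Per-class weights of a network
#'
#' Returns the individual synaptic weights of one plastic class, e.g. for
#' comparing recurrent weight distributions across training conditions.
#'
#' @inheritParams weight_class_mean
#' @return numeric vector of weights.
#' @export
class_weights <- function(net, class = "TT") {
  k <- net$plastic$class == class
  net$W[cbind(net$plastic$post[k], net$plastic$pre[k])]
}

#' Count synapses per connection class
#'
#' Topology statistic used to verify that two builds differ only in their
#' sampled initial weights, and that intra-column synapse counts scale
#' linearly with the number of columns.
#'
#' @param net a \code{timer_network}.
#' @return named integer vector: non-zero synapse count by (pre-class ->
#'   post-class) pair.
#' @export
synapse_counts <- function(net) {
  nz <- which(net$W != 0, arr.ind = TRUE)
  pre <- net$labels$class[nz[, 2]]
  post <- net$labels$class[nz[, 1]]
  table(paste(pre, post, sep = "->"))
}

#' Aggregate synaptic conductances for a given activation state
#'
#' Computes the per-neuron excitatory and inhibitory conductances
#' \eqn{g_{E,i} = \sum_j W_{ij} s_j} (over excitatory presynaptic partners
#' and input channels) and \eqn{g_{I,i}} (over inhibitory partners), the
#' quantities entering the membrane equation.  This R implementation mirrors
#' the incremental bookkeeping inside the compiled integrator and exists for
#' inspection and testing.
#'
#' @param net a \code{timer_network}.
#' @param s per-neuron synaptic activation in [0, 1].
#' @param s_in per-input-channel activation (default all zero).
#' @return list with numeric vectors \code{g_E} and \code{g_I}.
#' @export
aggregate_conductances <- function(net, s, s_in = NULL) {
  stopifnot(length(s) == nrow(net$labels), all(s >= 0), all(s <= 1))
  exc <- net$sclass != 1L
  g_E <- as.vector(net$W[, exc, drop = FALSE] %*% s[exc])
  g_I <- as.vector(net$W[, !exc, drop = FALSE] %*% s[!exc])
  if (!is.null(s_in)) g_E <- g_E + as.vector(net$Win %*% s_in)
  list(g_E = g_E, g_I = g_I)
}

#' Save / load a network snapshot
#'
#' Writes the weight matrix (and input weights) as plain tab-separated text
#' with a JSON sidecar of metadata (seed, column count, configuration), a
#' portable container that round-trips through \code{load_network}.
#'
#' @param net a \code{timer_network}.
#' @param path directory to write into (created if needed).
#' @return \code{save_network} returns \code{path} invisibly;
#'   \code{load_network} returns the reconstructed \code{timer_network}.
#' @export
save_network <- function(net, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(net$W, file.path(path, "weights.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(net$Win, file.path(path, "input_weights.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(n_columns = net$n_columns, seed = net$seed,
               trained = net$trained, targets = net$targets,
               config = unclass(net$config),
               package_version = as.character(utils::packageVersion("timernet")))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  class(cfg) <- c("timernet_config", "list")
  net <- build_network(meta$n_columns, cfg, seed = meta$seed)
  W <- as.matrix(utils::read.table(file.path(path, "weights.tsv"),
                                   sep = "\t"))
  dimnames(W) <- NULL
  Win <- as.matrix(utils::read.table(file.path(path, "input_weights.tsv"),
                                     sep = "\t"))
  dimnames(Win) <- NULL
  net$W <- W
  net$Win <- Win
  # learned launch synapses ignite the next column's envelope in
  # proportion to their strength
  mt <- net$plastic$class == "MT"
  if (any(mt)) {
    widx <- cbind(net$plastic$post[mt], net$plastic$pre[mt])
    net$Y_launch[widx] <- cfg$input$rho_y_launch *
      pmin(W[widx] / cfg$architecture$w_MT_max, 1)
  }
  net$trained <- isTRUE(meta$trained)
  if (!is.null(meta$targets)) net$targets <- meta$targets
  net
}
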