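# Directed skills networks: edge assembly from coefficient posteriors,
# credible-interval pruning, activation/instrength/outstrength, layout, I/O.
#
# Edge direction convention: the coefficient of predictor skill k in the
# node-wise model for outcome skill j is the k -> j edge, so W[k, j] holds the
# weight of edge k -> j (rows = source, columns = target).

#' Prune edges by equal-tailed credible interval
#'
#' An edge is retained iff the equal-tailed interval at the given level,
#' computed from empirical quantiles of its coefficient draws, excludes zero.
#'
#' @param draws Numeric vector of posterior draws for one edge, or a matrix
#'   with one column per edge.
#' @param level Credible level in (0, 1), default 0.95.
#' @return List with \code{retain} (logical), \code{ci_low}, \code{ci_high}.
#' @export
#' @examples
#' prune_edges(rep(0.3, 1000))$retain          # TRUE
#' prune_edges(rnorm(1000))$retain             # FALSE
prune_edges <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  m <- as.matrix(draws)
  a <- (1 - level) / 2
  q <- apply(m, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  lo <- q[1, ]; hi <- q[2, ]
  list(retain = lo > 0 | hi < 0, ci_low = lo, ci_high = hi)
}

# Collect, for a nodewise_set, a draws matrix of all K*(K-1) directed edges.
# extract(fit) must return a draws x (K-1) matrix of slope draws for that fit.
edge_draws_matrix <- function(fits, extract) {
  K <- fits$n_skills
  cols <- list()
  for (j in seq_len(K)) {
    sl <- extract(fits$fits[[j]])        # draws x (K-1), predictors of node j
    colnames(sl) <- paste(colnames(sl), skill_cols(K)[j], sep = "->")
    cols[[j]] <- sl
  }
  do.call(cbind, cols)
}

assemble_network <- function(fits, edge_means, edge_draws, activation, level,
                             id, type) {
  K <- fits$n_skills
  sk <- skill_cols(K)
  W <- matrix(0, K, K, dimnames = list(sk, sk))
  retain <- matrix(FALSE, K, K, dimnames = list(sk, sk))
  ci_low <- ci_high <- matrix(NA_real_, K, K, dimnames = list(sk, sk))
  pr <- prune_edges(edge_draws, level)
  nm <- colnames(edge_draws)
  src <- sub("->.*$", "", nm)
  tgt <- sub("^.*->", "", nm)
  for (e in seq_along(nm)) {
    W[src[e], tgt[e]] <- edge_means[e]
    retain[src[e], tgt[e]] <- pr$retain[e]
    ci_low[src[e], tgt[e]] <- pr$ci_low[e]
    ci_high[src[e], tgt[e]] <- pr$ci_high[e]
  }
  Wr <- W * retain
  structure(list(
    physician_id = id, type = type, level = level,
    skills = skill_labels(K),
    W = W, retain = retain, ci_low = ci_low, ci_high = ci_high,
    activation = activation,
    instrength = colSums(Wr), outstrength = rowSums(Wr),
    instrength_raw = colSums(W), outstrength_raw = rowSums(W),
    layout = NULL
  ), class = "sdm_network")
}

#' Build one physician's directed skills network
#'
#' Edge weights are the posterior means of that physician's coefficients
#' (population + physician deviation per retained iteration); pruning uses the
#' physician-specific coefficient draws by default. Activation is the
#' physician's mean (post-imputation) rating per skill; instrength and
#' outstrength sum the retained incoming/outgoing edge weights.
#'
#' @param fits A \code{\link{fit_all_nodes}} result.
#' @param ratings The (complete) rating table the fits were estimated on.
#' @param physician_id Physician to build the network for.
#' @param level Credible level for edge pruning (default 0.95).
#' @param prune_by \code{"physician"} (default): prune by physician-specific
#'   coefficient draws; \code{"population"}: prune by population draws.
#' @return An object of class \code{sdm_network}.
#' @export
build_physician_network <- function(fits, ratings, physician_id, level = 0.95,
                                    prune_by = c("physician", "population")) {
  stopifnot(inherits(fits, "nodewise_set"))
  prune_by <- match.arg(prune_by)
  if (!physician_id %in% fits$physician_ids) {
    stopf("physician %s not present in the fits", physician_id)
  }
  rows <- ratings$physician_id == physician_id
  if (!any(rows)) stopf("physician %s not present in the ratings", physician_id)
  activation <- colMeans(rating_matrix(ratings)[rows, , drop = FALSE])

  phys_draws <- edge_draws_matrix(fits, function(f) {
    f$b[, physician_id, f$predictors, drop = TRUE]
  })
  prune_draws <- if (prune_by == "physician") phys_draws else {
    edge_draws_matrix(fits, function(f) f$beta[, f$predictors, drop = FALSE])
  }
  assemble_network(fits, colMeans(phys_draws), prune_draws, activation, level,
                   id = physician_id, type = "physician")
}

#' Build the population skills network
#'
#' By default uses the population-level (fixed-effect) coefficient posteriors
#' as edge weights and prunes by population draws; activation is the mean of
#' the per-physician activations (equal weight per physician). The
#' \code{"average"} method instead averages the physician-specific coefficient
#' draws across physicians per iteration.
#'
#' @inheritParams build_physician_network
#' @param method \code{"population"} (fixed effects, default) or
#'   \code{"average"} (mean of physician-specific draws).
#' @return An object of class \code{sdm_network} with
#'   \code{physician_id = "population"}.
#' @export
build_population_network <- function(fits, ratings, level = 0.95,
                                     method = c("population", "average")) {
  stopifnot(inherits(fits, "nodewise_set"))
  method <- match.arg(method)
  acts <- sapply(fits$physician_ids, function(id) {
    colMeans(rating_matrix(ratings)[ratings$physician_id == id, , drop = FALSE])
  })
  activation <- rowMeans(acts)

  draws <- if (method == "population") {
    edge_draws_matrix(fits, function(f) f$beta[, f$predictors, drop = FALSE])
  } else {
    edge_draws_matrix(fits, function(f) {
      apply(f$b[, , f$predictors, drop = FALSE], c(1, 3), mean)
    })
  }
  assemble_network(fits, colMeans(draws), draws, activation, level,
                   id = "population", type = "population")
}

#' @export
print.sdm_network <- function(x, ...) {
  cat(sprintf("Skills network (%s: %s), %d nodes, %d/%d edges retained at %g%% CI\n",
              x$type, x$physician_id, length(x$skills),
              sum(x$retain), sum(upper.tri(x$W) | lower.tri(x$W)),
              100 * x$level))
  df <- data.frame(skill = seq_along(x$skills),
                   activation = round(x$activation, 2),
                   instrength = round(x$instrength, 2),
                   outstrength = round(x$outstrength, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Network node parameters as a data frame
#'
#' @param network An \code{sdm_network}.
#' @return Data frame: skill index, label, activation, instrength, outstrength.
#' @export
network_params <- function(network) {
  stopifnot(inherits(network, "sdm_network"))
  data.frame(
    physician_id = network$physician_id,
    skill = seq_along(network$skills),
    label = network$skills,
    activation = unname(network$activation),
    instrength = unname(network$instrength),
    outstrength = unname(network$outstrength),
    stringsAsFactors = FALSE
  )
}

network_igraph <- function(network, retained_only = TRUE) {
  K <- length(network$skills)
  sk <- skill_cols(K)
  keep <- if (retained_only) network$retain else (row(network$W) != col(network$W))
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = sk[idx[, 1]], to = sk[idx[, 2]],
                      weight = network$W[idx],
                      retained = network$retain[idx],
                      ci_low = network$ci_low[idx],
                      ci_high = network$ci_high[idx],
                      stringsAsFactors = FALSE)
  vertices <- data.frame(name = sk, label = network$skills,
                         activation = unname(network$activation),
                         stringsAsFactors = FALSE)
  if (!is.null(network$layout)) {
    vertices$x <- network$layout[, 1]
    vertices$y <- network$layout[, 2]
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Lay out a skills network with the Fruchterman-Reingold algorithm
#'
#' Force-directed placement in which absolute edge weights act as attraction
#' strengths, so strongly associated skills end up close together.
#' Deterministic given the seed.
#'
#' @param network An \code{sdm_network}.
#' @param seed Integer seed for the layout's random initialization.
#' @param niter Iterations of the layout algorithm.
#' @return The network with a \code{$layout} matrix (nodes x 2) filled in.
#' @export
layout_network <- function(network, seed = 1L, niter = 500L) {
  stopifnot(inherits(network, "sdm_network"))
  g <- network_igraph(network, retained_only = TRUE)
  w <- abs(igraph::E(g)$weight)
  coords <- with_seed(seed, {
    igraph::layout_with_fr(g, niter = niter,
                           weights = if (length(w)) w else NULL)
  })
  rownames(coords) <- skill_cols(length(network$skills))
  network$layout <- coords
  network
}

#' @export
plot.sdm_network <- function(x, edge_scale = 8, ...) {
  if (is.null(x$layout)) x <- layout_network(x)
  g <- network_igraph(x, retained_only = TRUE)
  w <- abs(igraph::E(g)$weight)
  igraph::plot.igraph(
    g, layout = x$layout,
    vertex.label = seq_along(x$skills),
    vertex.size = 12 + 3 * (x$activation - mean(x$activation)),
    edge.width = if (length(w)) edge_scale * w / max(w) else 1,
    edge.arrow.size = 0.4, ...
  )
  invisible(x)
}

#' Export a skills network to file
#'
#' Formats: \code{"csv"} (edge list of retained edges:
#' source_skill, target_skill, weight, retained, ci_low, ci_high),
#' \code{"graphml"} (all edges plus node attributes label/activation/x/y) and
#' \code{"json"} (lossless bundle of every field). JSON and GraphML round-trip
#' through \code{\link{import_network}}.
#'
#' @param network An \code{sdm_network}.
#' @param path Output file.
#' @param format One of \code{"csv"}, \code{"graphml"}, \code{"json"};
#'   guessed from the extension when missing.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(network, path, format = c("json", "graphml", "csv")) {
  stopifnot(inherits(network, "sdm_network"))
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("json", "graphml", "csv")) ext else "json"
  }
  format <- match.arg(format)
  if (format == "csv") {
    g <- network_igraph(network, retained_only = TRUE)
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("source_skill", "target_skill")
    write.csv(el, path, row.names = FALSE)
  } else if (format == "graphml") {
    g <- network_igraph(network, retained_only = FALSE)
    igraph::E(g)$retained <- as.integer(igraph::E(g)$retained)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    x <- unclass(network)
    for (f in c("W", "retain", "ci_low", "ci_high")) x[[f]] <- unname(x[[f]])
    if (!is.null(x$layout)) x$layout <- unname(x$layout)
    jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  }
  invisible(path)
}

#' Import a skills network written by \code{\link{export_network}}
#'
#' @param path File path (.json or .graphml).
#' @return An \code{sdm_network}.
#' @export
import_network <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    K <- length(x$skills)
    sk <- skill_cols(K)
    for (f in c("W", "retain", "ci_low", "ci_high")) {
      x[[f]] <- matrix(unlist(x[[f]]), K, K, byrow = FALSE,
                       dimnames = list(sk, sk))
      if (f == "retain") x[[f]] <- matrix(as.logical(x[[f]]), K, K,
                                          dimnames = list(sk, sk))
    }
    # jsonlite reads row-major matrices back as-is via simplifyVector
    for (f in c("activation", "instrength", "outstrength",
                "instrength_raw", "outstrength_raw")) {
      x[[f]] <- setNames(as.numeric(x[[f]]), sk)
    }
    if (!is.null(x$layout)) {
      x$layout <- matrix(unlist(x$layout), K, 2, dimnames = list(sk, NULL))
    }
    structure(x, class = "sdm_network")
  } else if (ext == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vs <- igraph::as_data_frame(g, what = "vertices")
    es <- igraph::as_data_frame(g, what = "edges")
    K <- nrow(vs)
    sk <- skill_cols(K)
    ord <- match(sk, vs$name)
    W <- matrix(0, K, K, dimnames = list(sk, sk))
    retain <- matrix(FALSE, K, K, dimnames = list(sk, sk))
    ci_low <- ci_high <- matrix(NA_real_, K, K, dimnames = list(sk, sk))
    for (e in seq_len(nrow(es))) {
      W[es$from[e], es$to[e]] <- es$weight[e]
      retain[es$from[e], es$to[e]] <- es$retained[e] > 0
      ci_low[es$from[e], es$to[e]] <- es$ci_low[e]
      ci_high[es$from[e], es$to[e]] <- es$ci_high[e]
    }
    Wr <- W * retain
    layout <- if (!is.null(vs$x)) {
      matrix(c(vs$x[ord], vs$y[ord]), K, 2, dimnames = list(sk, NULL))
    } else NULL
    structure(list(
      physician_id = NA_character_, type = "imported", level = NA_real_,
      skills = vs$label[ord],
      W = W, retain = retain, ci_low = ci_low, ci_high = ci_high,
      activation = setNames(vs$activation[ord], sk),
      instrength = colSums(Wr), outstrength = rowSums(Wr),
      instrength_raw = colSums(W), outstrength_raw = rowSums(W),
      layout = layout
    ), class = "sdm_network")
  } else {
    stopf("cannot import format '%s' (use json or graphml)", ext)
  }
}
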