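#' Train a self-organizing map on encoded reads
#'
#' Fits a two-dimensional SOM codebook to one-hot encoded amplicon reads using
#' the soft-Hamming distance d(read, node) = sum over positions of
#' (1 - node weight at the read's base). Node profiles are position-weight
#' matrices; they are initialised from reads sampled with replacement and
#' updated towards each presented read within a Gaussian grid neighbourhood.
#' The learning rate decays linearly from \code{alpha[1]} to \code{alpha[2]}
#' and the neighbourhood radius from \code{sigma[1]} (default half the larger
#' grid dimension) to \code{sigma[2]} over the training rounds. When a node
#' profile is one-hot, the soft-Hamming distance equals the integer Hamming
#' distance to the node's consensus sequence.
#'
#' @param encoded an \code{\link{encode_reads}} object.
#' @param grid integer vector \code{c(rows, cols)}; default 20 x 20.
#' @param rounds number of training rounds (default 10000). In
#'   \code{mode = "presentations"} each round presents one uniformly sampled
#'   read; in \code{mode = "epochs"} each round presents every read once in
#'   random order.
#' @param seed integer seed controlling initialisation and presentation order.
#' @param alpha numeric length-2 learning-rate schedule (start, end).
#' @param sigma neighbourhood radius schedule (start, end); default
#'   \code{c(max(grid)/2, 0.5)}.
#' @param mode \code{"presentations"} (default) or \code{"epochs"}.
#' @return An object of class \code{som_codebook}: list with \code{weights}
#'   (nodes x (width * 5) matrix, nodes in row-major grid order), \code{grid},
#'   \code{rounds}, \code{seed}, \code{alpha}, \code{sigma}, \code{mode},
#'   \code{width}, \code{nsym}. After training every node's per-position
#'   weights sum to 1.
#' @seealso \code{\link{assign_to_nodes}}, \code{\link{cluster_reads}}
#' @export
train_som <- function(encoded, grid = c(20L, 20L), rounds = 10000L, seed = 1L,
                      alpha = c(0.5, 0.01), sigma = NULL,
                      mode = c("presentations", "epochs")) {
  stopifnot(inherits(encoded, "encoded_reads"))
  mode <- match.arg(mode)
  if (length(grid) != 2L) stopf("'grid' must be c(rows, cols)")
  grid <- c(check_count(grid[1], "grid rows"), check_count(grid[2], "grid cols"))
  rounds <- check_count(rounds, "rounds", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  if (length(alpha) != 2L || any(alpha <= 0) || any(alpha > 1))
    stopf("'alpha' must be two values in (0, 1]")
  if (is.null(sigma)) sigma <- c(max(grid) / 2, 0.5)
  if (length(sigma) != 2L || any(sigma <= 0)) stopf("'sigma' must be two positive values")

  n <- nrow(encoded$codes)
  n_nodes <- grid[1] * grid[2]
  set.seed(seed)
  init_idx <- sample.int(n, n_nodes, replace = TRUE)
  present <- if (mode == "presentations") {
    sample.int(n, rounds, replace = TRUE)
  } else {
    as.vector(vapply(seq_len(rounds), function(i) sample.int(n, n), integer(n)))
  }
  w <- C_som_train(encoded$codes, init_idx, present, grid[1], grid[2],
                   alpha[1], alpha[2], sigma[1], sigma[2], 5L)
  structure(list(weights = w, grid = grid, rounds = rounds, seed = seed,
                 alpha = alpha, sigma = sigma, mode = mode,
                 width = encoded$width, nsym = 5L),
            class = "som_codebook")
}

#' Consensus sequences of a SOM codebook
#'
#' Per node, the sequence of per-position argmax weights (ties resolved to the
#' alphabetically first base).
#'
#' @param codebook a \code{som_codebook}.
#' @return character vector of length \code{prod(grid)}, row-major node order.
#' @export
som_consensus <- function(codebook) {
  stopifnot(inherits(codebook, "som_codebook"))
  w <- codebook$weights
  L <- codebook$width; nsym <- codebook$nsym
  codes <- matrix(0L, nrow = nrow(w), ncol = L)
  for (p in seq_len(L)) {
    block <- w[, (p - 1L) * nsym + seq_len(nsym), drop = FALSE]
    codes[, p] <- max.col(block, ties.method = "first")
  }
  codes_to_seq(codes)
}

#' Map encoded reads to their best-matching SOM nodes
#'
#' Each read is assigned to the node with minimal soft-Hamming distance; ties
#' are broken by the smallest (row, col) coordinate in row-major order. Nodes
#' with no assigned reads yield no cluster.
#'
#' @param encoded an \code{encoded_reads} object; its width must match the
#'   codebook.
#' @param codebook a trained \code{som_codebook}.
#' @return An object of class \code{read_clusters} holding, per non-empty
#'   node, the member read indices; cohesion and representatives are filled in
#'   by \code{\link{cluster_cohesion}} / \code{\link{cluster_reads}}.
#' @export
assign_to_nodes <- function(encoded, codebook) {
  stopifnot(inherits(encoded, "encoded_reads"), inherits(codebook, "som_codebook"))
  if (encoded$width != codebook$width)
    stopf("encoding width %d does not match codebook width %d",
          encoded$width, codebook$width)
  res <- C_som_assign(encoded$codes, codebook$weights, codebook$nsym)
  node <- res$node
  grid <- codebook$grid
  row <- (node - 1L) %/% grid[2] + 1L
  col <- (node - 1L) %% grid[2] + 1L
  occupied <- sort(unique(node))
  members <- split(seq_len(nrow(encoded$codes)), factor(node, levels = occupied))
  ids <- sprintf("n%02d_%02d", (occupied - 1L) %/% grid[2] + 1L,
                 (occupied - 1L) %% grid[2] + 1L)
  names(members) <- ids
  structure(list(members = members,
                 node = stats::setNames(occupied, ids),
                 grid = grid,
                 assignment = data.frame(id = encoded$ids, node = node,
                                         row = row, col = col,
                                         distance = res$distance,
                                         stringsAsFactors = FALSE),
                 cohesion = NULL, representative = NULL,
                 subcluster = stats::setNames(rep(FALSE, length(members)), ids)),
            class = "read_clusters")
}

#' @export
predict.som_codebook <- function(object, encoded, ...) {
  assign_to_nodes(encoded, object)
}

#' @export
print.som_codebook <- function(x, ...) {
  cat(sprintf("som_codebook: %d x %d grid, width %d nt, %d %s, seed %d\n",
              x$grid[1], x$grid[2], x$width, x$rounds, x$mode, x$seed))
  invisible(x)
}

#' @method summary som_codebook
#' @export
summary.som_codebook <- function(object, ...) {
  sharp <- rowMeans(vapply(seq_len(object$width), function(p) {
    block <- object$weights[, (p - 1L) * object$nsym + seq_len(object$nsym), drop = FALSE]
    apply(block, 1L, max)
  }, numeric(nrow(object$weights))))
  out <- list(grid = object$grid, rounds = object$rounds, mode = object$mode,
              node_sharpness = summary(sharp))
  class(out) <- "summary.som_codebook"
  out
}

#' @export
print.summary.som_codebook <- function(x, ...) {
  cat(sprintf("SOM codebook %d x %d (%d %s)\n", x$grid[1], x$grid[2],
              x$rounds, x$mode))
  cat("per-node mean max position weight (1 = fully crisp):\n")
  print(x$node_sharpness)
  invisible(x)
}

#' @method plot som_codebook
#' @export
plot.som_codebook <- function(x, encoded = NULL, ...) {
  grid <- x$grid
  if (is.null(encoded)) {
    sharp <- rowMeans(vapply(seq_len(x$width), function(p) {
      block <- x$weights[, (p - 1L) * x$nsym + seq_len(x$nsym), drop = FALSE]
      apply(block, 1L, max)
    }, numeric(nrow(x$weights))))
    z <- matrix(sharp, nrow = grid[1], ncol = grid[2], byrow = TRUE)
    graphics::image(seq_len(grid[2]), seq_len(grid[1]), t(z),
                    xlab = "grid column", ylab = "grid row",
                    main = "node profile crispness", ...)
  } else {
    a <- assign_to_nodes(encoded, x)
    counts <- matrix(0L, grid[1], grid[2])
    tab <- table(a$assignment$row, a$assignment$col)
    counts[cbind(as.integer(rownames(tab))[row(tab)],
                 as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
    graphics::image(seq_len(grid[2]), seq_len(grid[1]), t(counts),
                    xlab = "grid column", ylab = "grid row",
                    main = "node occupancy", ...)
  }
  invisible(x)
}
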