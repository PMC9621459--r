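# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Values are plain numeric arrays; spatial tensors use the (H, W, C, N)
# layout and dense tensors the (N, F) matrix layout. Every operation
# appends a node to the tape; `ad_backward()` walks the tape in reverse
# creation order, which is always a valid reverse topological order for
# define-by-run graphs.

ad_tape <- function(guided_relu = FALSE) {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 64L)
  tape$n <- 0L
  tape$guided_relu <- guided_relu
  tape
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd$id <- n
  nd
}

# Leaf holding a constant or a parameter; parameters are just leaves whose
# gradient the caller reads after the backward pass.
ad_leaf <- function(tape, value) ad_node(tape, value)

# gradient of a node after a backward pass; zeros when the output did not
# depend on it
node_grad <- function(node) {
  if (is.null(node$grad)) {
    g <- node$value
    g[] <- 0
    g
  } else {
    node$grad
  }
}

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run the backward pass from a node
#'
#' Seeds the node's gradient (with 1 for scalars, or `seed` when given) and
#' propagates gradients to every upstream leaf on the tape.
#' @param tape tape returned by the forward pass
#' @param node output node to differentiate
#' @param seed optional gradient seed with the same shape as `node$value`
#' @keywords internal
ad_backward <- function(tape, node, seed = NULL) {
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  if (is.null(seed)) {
    seed <- node$value
    seed[] <- 1
  }
  node$grad <- seed
  for (i in seq(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}
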