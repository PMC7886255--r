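#' Construct a synchronous Boolean network
#'
#' A Boolean network \eqn{G(V, F)} has \eqn{n} binary nodes (genes) and one
#' update function per node, stored here as an explicit truth table over
#' that node's input nodes. All nodes update synchronously:
#' \eqn{v_i(t+1) = f_i(v(t))}.
#'
#' Truth tables are little-endian in the input list: the first listed
#' input is the lowest-order bit of the table address, so for inputs
#' `(a, b)` the table rows correspond to `(a,b) = (0,0), (1,0), (0,1),
#' (1,1)` in that order.
#'
#' @param node_names character vector of n node identifiers.
#' @param inputs list of n integer vectors; `inputs[[i]]` are the indices
#'   of the nodes feeding \eqn{f_i} (the indegree is `length(inputs[[i]])`).
#' @param tables list of n 0/1 vectors; `tables[[i]]` has
#'   `2^length(inputs[[i]])` entries.
#' @return an object of class `boolean_network`.
#' @seealso [read_boolean_rules()] for the logic-expression file format.
#' @export
boolean_network <- function(node_names, inputs, tables) {
  n <- length(node_names)
  stopifnot(n >= 1L, length(inputs) == n, length(tables) == n)
  if (anyDuplicated(node_names)) stop("node names must be unique")
  inputs <- lapply(inputs, as.integer)
  tables <- lapply(tables, as.integer)
  for (i in seq_len(n)) {
    if (length(inputs[[i]]) > 0L &&
        (min(inputs[[i]]) < 1L || max(inputs[[i]]) > n))
      stop(sprintf("node %d: input index out of range", i))
    if (length(tables[[i]]) != 2L^length(inputs[[i]]))
      stop(sprintf("node %d: truth table must have 2^indegree = %d entries",
                   i, 2L^length(inputs[[i]])))
    if (!all(tables[[i]] %in% c(0L, 1L)))
      stop(sprintf("node %d: truth table entries must be 0/1", i))
  }
  structure(list(node_names = as.character(node_names),
                 inputs = inputs, tables = tables, n = n),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: n = %d nodes, max indegree H = %d\n",
              x$n, max(vapply(x$inputs, length, 0L))))
  cat("  nodes:", paste(x$node_names, collapse = ", "), "\n")
  invisible(x)
}

# Allowed operators in rule expressions, mapped onto logical R calls.
.bn_transform_expr <- function(e, node_names) {
  if (is.symbol(e)) {
    if (!(as.character(e) %in% node_names))
      stop(sprintf("unknown node name '%s' in rule expression", as.character(e)))
    return(e)
  }
  if (is.numeric(e) || is.logical(e)) {
    if (!(e %in% c(0, 1, TRUE, FALSE))) stop("only constants 0/1 allowed")
    return(as.logical(e))
  }
  if (!is.call(e)) stop("malformed rule expression")
  op <- as.character(e[[1L]])
  args <- lapply(as.list(e)[-1L], .bn_transform_expr, node_names = node_names)
  switch(op,
    "(" = args[[1L]],
    "!" = as.call(c(quote(`!`), args)),
    "&" = , "&&" = as.call(c(quote(`&`), args)),
    "|" = , "||" = as.call(c(quote(`|`), args)),
    "^" = as.call(c(quote(xor), args)),
    stop(sprintf("operator '%s' not allowed in rule expressions", op)))
}

#' Read a Boolean network from a plain-text rule file
#'
#' One line per node, `name, <logic expression>`, where the expression
#' uses node names and the operators `&` (AND), `|` (OR), `!` (NOT),
#' `^` (XOR) and parentheses. Lines starting with `#` are comments.
#' Expressions are compiled to per-node truth tables; inputs are stored
#' in order of first appearance in the expression (little-endian
#' addressing, see [boolean_network()]).
#'
#' @param path path to a rule file, or `NULL` if `text` is given.
#' @param text optional character vector of rule lines (instead of a file).
#' @return a `boolean_network`.
#' @examples
#' net <- read_boolean_rules(text = c("v1, !v2", "v2, !v1 | v3", "v3, v1"))
#' transition_table(net)
#' @export
read_boolean_rules <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no rules found")
  parts <- regmatches(lines, regexpr(",", lines), invert = TRUE)
  if (any(vapply(parts, length, 0L) != 2L))
    stop("each rule line must be 'name, expression'")
  node_names <- trimws(vapply(parts, `[`, "", 1L))
  expr_txt <- trimws(vapply(parts, `[`, "", 2L))
  n <- length(node_names)
  inputs <- vector("list", n)
  tables <- vector("list", n)
  for (i in seq_len(n)) {
    e <- tryCatch(str2lang(expr_txt[i]),
                  error = function(c) stop(sprintf(
                    "cannot parse rule for '%s': %s", node_names[i], expr_txt[i])))
    e <- .bn_transform_expr(e, node_names)
    vars <- unique(all.vars(e))
    # order of first appearance in the expression text
    pos <- vapply(vars, function(v)
      regexpr(paste0("\\b", v, "\\b"), expr_txt[i]), 0L)
    vars <- vars[order(pos)]
    inputs[[i]] <- match(vars, node_names)
    h <- length(vars)
    tab <- integer(2L^h)
    for (a in seq_len(2L^h)) {
      bits <- as.logical(bitwAnd(bitwShiftR(a - 1L, seq_len(h) - 1L), 1L))
      env <- as.list(stats::setNames(bits, vars))
      tab[a] <- as.integer(eval(e, envir = env))
    }
    tables[[i]] <- tab
  }
  boolean_network(node_names, inputs, tables)
}

#' One synchronous update step
#'
#' Applies every node's update function to the same input state and
#' returns the successor Gene Activity Profile.
#'
#' @param network a `boolean_network`.
#' @param state 0/1 vector of length `network$n`.
#' @return 0/1 integer vector, the state at time t+1.
#' @export
bn_step <- function(network, state) {
  stopifnot(inherits(network, "boolean_network"))
  state <- as.integer(state)
  if (length(state) != network$n)
    stop(sprintf("state length %d does not match network size %d",
                 length(state), network$n))
  if (!all(state %in% c(0L, 1L))) stop("state must be 0/1")
  vapply(seq_len(network$n), function(i) {
    ins <- network$inputs[[i]]
    addr <- if (length(ins) == 0L) 1L else
      1L + sum(state[ins] * 2L^(seq_along(ins) - 1L))
    network$tables[[i]][addr]
  }, 0L)
}

# state <-> integer code, v1 as the most significant bit so that code
# order equals lexicographic order of the state vector
.bn_code <- function(state, n) sum(state * 2L^((n - 1L):0L))
.bn_decode <- function(code, n)
  bitwAnd(bitwShiftR(code, (n - 1L):0L), 1L)

# successor code for every global state 0 .. 2^n - 1, vectorized
.bn_successors <- function(network) {
  n <- network$n
  codes <- 0:(2L^n - 1L)
  nxt <- integer(length(codes))
  for (i in seq_len(n)) {
    ins <- network$inputs[[i]]
    addr <- rep(1L, length(codes))
    for (k in seq_along(ins))
      addr <- addr + bitwAnd(bitwShiftR(codes, n - ins[k]), 1L) * 2L^(k - 1L)
    nxt <- nxt + network$tables[[i]][addr] * 2L^(n - i)
  }
  nxt
}

#' Full state-transition table
#'
#' Enumerates all \eqn{2^n} global states in ascending binary order (node
#' 1 the most significant bit) together with their synchronous
#' successors. Refuses when the state space is too large.
#'
#' @param network a `boolean_network`.
#' @param limit maximum node count for exhaustive enumeration (default 20).
#' @return a data.frame with columns `v<i>` (state at t) and
#'   `v<i>_next` (state at t+1); `2^n` rows. Write with
#'   [utils::write.table()] for a TSV export.
#' @export
transition_table <- function(network, limit = 20L) {
  stopifnot(inherits(network, "boolean_network"))
  n <- network$n
  if (n > limit)
    stop(sprintf(
      "state space 2^%d exceeds the exhaustive limit (limit = %d nodes)",
      n, limit))
  codes <- 0:(2L^n - 1L)
  nxt <- .bn_successors(network)
  bits <- function(v)
    matrix(vapply(v, .bn_decode, integer(n), n = n), ncol = n, byrow = TRUE)
  out <- data.frame(bits(codes), bits(nxt))
  names(out) <- c(paste0("v", seq_len(n)), paste0("v", seq_len(n), "_next"))
  out
}

#' Enumerate all attractors of a Boolean network
#'
#' Exhaustively follows every trajectory of the synchronous dynamics (a
#' functional graph on the \eqn{2^n} states) and extracts every cycle
#' exactly once. Each attractor is rotated to start at its
#' lexicographically smallest state and attractors are sorted by that
#' state, so output order is deterministic.
#'
#' @param network a `boolean_network`.
#' @param limit maximum node count for exhaustive enumeration (default 20).
#' @return an [attractor_set()]; singleton attractors have period 1.
#' @examples
#' net <- read_boolean_rules(text = c("v1, !v2", "v2, !v1 | v3", "v3, v1"))
#' enumerate_attractors(net)
#' @export
enumerate_attractors <- function(network, limit = 20L) {
  stopifnot(inherits(network, "boolean_network"))
  n <- network$n
  if (n > limit)
    stop(sprintf(
      "state space 2^%d exceeds the exhaustive limit (limit = %d nodes)",
      n, limit))
  nxt <- .bn_successors(network)          # 0-based codes
  nstates <- 2L^n
  status <- integer(nstates)              # 0 unvisited, 1 on stack, 2 done
  cycles <- list()
  for (s0 in seq_len(nstates)) {
    if (status[s0] != 0L) next
    path <- integer(0)
    s <- s0
    while (status[s] == 0L) {
      status[s] <- 1L
      path <- c(path, s)
      s <- nxt[s] + 1L
    }
    if (status[s] == 1L) {                # new cycle closes within this path
      k <- match(s, path)
      cycles[[length(cycles) + 1L]] <- path[k:length(path)] - 1L
    }
    status[path] <- 2L
  }
  mats <- lapply(cycles, function(cyc) {
    r <- which.min(cyc)                   # rotate to lexicographic minimum
    cyc <- c(cyc[r:length(cyc)], cyc[seq_len(r - 1L)])
    matrix(vapply(cyc, .bn_decode, integer(n), n = n), ncol = n, byrow = TRUE)
  })
  mats <- mats[order(vapply(cycles, function(cyc) as.integer(min(cyc)), 0L))]
  attractor_set(mats)
}
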