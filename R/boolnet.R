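# Boolean gene-regulatory-network engine: rule parsing, truth-table
# compilation, stochastic asynchronous settling, fixed-point enumeration.

MAX_RULE_INPUTS <- 16L
MAX_ENUM_GENES <- 20L

#' Parse a Boolean network from BoolNet-style rule text
#'
#' Reads the de facto standard `"targets, factors"` text format for Boolean
#' gene-regulatory networks: a header line followed by one line per gene of
#' the form `Gene, expression`, where the expression combines gene names with
#' `!` (not), `&` (and), `|` (or), parentheses, and the constants `0`/`1`.
#' Each rule is compiled to a truth table over its referenced genes, so later
#' evaluation is a table lookup.
#'
#' @param rule_text Character scalar with the full rule text, or a character
#'   vector of lines. Use [load_network_file()] to read from disk.
#' @return An object of class `boolnet`: a list with `gene_names`, `n_genes`,
#'   `inputs` (per-gene integer vectors of regulator indices) and `tables`
#'   (per-gene 0/1 vectors of length `2^k` indexed by the regulator bits,
#'   first regulator least significant).
#' @examples
#' net <- load_network("targets, factors\nA, B\nB, A & !B")
#' evaluate_rule(net, c(0, 1), 1)
#' @export
load_network <- function(rule_text) {
  stopifnot(is.character(rule_text))
  lines <- if (length(rule_text) == 1L) strsplit(rule_text, "\n", fixed = TRUE)[[1]] else rule_text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("rule text needs a header line and at least one rule line")
  header <- tolower(gsub("\\s", "", lines[[1]]))
  if (!identical(header, "targets,factors"))
    stop("expected header 'targets, factors', got: ", lines[[1]])
  body <- lines[-1]

  targets <- character(length(body))
  exprs <- character(length(body))
  for (i in seq_along(body)) {
    cm <- regexpr(",", body[[i]], fixed = TRUE)
    if (cm < 0) stop("rule line without comma: ", body[[i]])
    targets[[i]] <- trimws(substr(body[[i]], 1L, cm - 1L))
    exprs[[i]] <- trimws(substr(body[[i]], cm + 1L, nchar(body[[i]])))
  }
  if (anyDuplicated(targets))
    stop("duplicate target gene: ", targets[anyDuplicated(targets)][1])
  asts <- lapply(seq_along(body), function(i) {
    parse_bool_expr(exprs[[i]], targets, context = targets[[i]])
  })
  net <- compile_network(targets, asts)
  net
}

#' @rdname load_network
#' @param path Path to a rule file.
#' @export
load_network_file <- function(path) {
  load_network(readLines(path, warn = FALSE))
}

# recursive-descent parser for  expr := term ('|' term)* ; term := fac ('&' fac)*
# fac := '!' fac | '(' expr ')' | gene | 0 | 1
parse_bool_expr <- function(text, gene_names, context = "") {
  toks <- tokenize_bool(text, context)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else ""
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expr <- function() {
    node <- term()
    while (peek() == "|") { advance(); node <- list(op = "or", l = node, r = term()) }
    node
  }
  term <- function() {
    node <- fac()
    while (peek() == "&") { advance(); node <- list(op = "and", l = node, r = fac()) }
    node
  }
  fac <- function() {
    t <- peek()
    if (t == "!") { advance(); return(list(op = "not", l = fac())) }
    if (t == "(") {
      advance(); node <- expr()
      if (peek() != ")") stop("missing ')' in rule for ", context)
      advance(); return(node)
    }
    if (t %in% c("0", "1")) { advance(); return(list(op = "const", value = as.integer(t))) }
    if (grepl("^[A-Za-z_][A-Za-z0-9_.]*$", t)) {
      advance()
      idx <- match(t, gene_names)
      if (is.na(idx)) stop("rule for ", context, " references undeclared gene: ", t)
      return(list(op = "gene", index = idx))
    }
    stop("unexpected token '", t, "' in rule for ", context)
  }
  node <- expr()
  if (pos <= length(toks))
    stop("trailing input '", peek(), "' in rule for ", context)
  node
}

tokenize_bool <- function(text, context) {
  m <- gregexpr("[A-Za-z_][A-Za-z0-9_.]*|[01]|[!&|()]|\\S", text)[[1]]
  if (m[1] < 0) stop("empty rule for ", context)
  toks <- regmatches(text, gregexpr("[A-Za-z_][A-Za-z0-9_.]*|[01]|[!&|()]|\\S", text))[[1]]
  bad <- toks[!grepl("^([A-Za-z_][A-Za-z0-9_.]*|[01!&|()])$", toks)]
  if (length(bad)) stop("invalid character '", bad[[1]], "' in rule for ", context)
  toks
}

eval_ast <- function(node, bits) {
  switch(node$op,
    const = node$value,
    gene = bits[[node$index]],
    not = 1L - eval_ast(node$l, bits),
    and = eval_ast(node$l, bits) & eval_ast(node$r, bits),
    or = eval_ast(node$l, bits) | eval_ast(node$r, bits)
  )
}

ast_genes <- function(node) {
  switch(node$op,
    const = integer(0),
    gene = node$index,
    not = ast_genes(node$l),
    sort(unique(c(ast_genes(node$l), ast_genes(node$r))))
  )
}

compile_network <- function(gene_names, asts) {
  n <- length(gene_names)
  inputs <- vector("list", n)
  tables <- vector("list", n)
  full <- integer(n)
  for (g in seq_len(n)) {
    idx <- ast_genes(asts[[g]])
    if (length(idx) > MAX_RULE_INPUTS)
      stop("rule for ", gene_names[[g]], " references more than ",
           MAX_RULE_INPUTS, " genes")
    inputs[[g]] <- as.integer(idx)
    k <- length(idx)
    tbl <- integer(2^k)
    for (code in 0:(2^k - 1)) {
      full[] <- 0L
      if (k > 0) full[idx] <- bitwAnd(bitwShiftR(code, 0:(k - 1)), 1L)
      tbl[code + 1L] <- as.integer(eval_ast(asts[[g]], full))
    }
    tables[[g]] <- tbl
  }
  structure(
    list(gene_names = gene_names, n_genes = n, inputs = inputs, tables = tables),
    class = "boolnet"
  )
}

#' @export
print.boolnet <- function(x, ...) {
  cat("Boolean network with", x$n_genes, "genes:",
      paste(x$gene_names, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a random Boolean network
#'
#' Each gene receives `k_inputs` distinct regulators drawn uniformly at random
#' and an independent uniform random truth table over them (a random Boolean
#' network in the Kauffman N-K sense).
#'
#' @param n_genes Number of genes.
#' @param k_inputs Regulators per gene, between 1 and `n_genes`.
#' @param seed Optional integer; if given the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return A `boolnet` object.
#' @export
random_network <- function(n_genes, k_inputs, seed = NULL) {
  stopifnot(n_genes >= 1)
  if (k_inputs < 1 || k_inputs > n_genes)
    stop("k_inputs must be between 1 and n_genes")
  draw <- function() {
    inputs <- vector("list", n_genes)
    tables <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      inputs[[g]] <- sort(sample.int(n_genes, k_inputs))
      tables[[g]] <- sample(0:1, 2^k_inputs, replace = TRUE)
    }
    structure(
      list(gene_names = paste0("G", seq_len(n_genes)), n_genes = as.integer(n_genes),
           inputs = inputs, tables = tables),
      class = "boolnet"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

check_gene_state <- function(net, state) {
  if (length(state) != net$n_genes)
    stop("state has length ", length(state), ", expected ", net$n_genes)
  if (!all(state %in% c(0, 1))) stop("state entries must be 0 or 1")
  as.integer(state)
}

#' Evaluate one gene's update rule at a state
#'
#' @param net A `boolnet` object.
#' @param state 0/1 vector of length `n_genes`.
#' @param gene_index Gene whose rule to evaluate (1-based).
#' @return The rule output, 0 or 1.
#' @export
evaluate_rule <- function(net, state, gene_index) {
  state <- check_gene_state(net, state)
  if (gene_index < 1 || gene_index > net$n_genes) stop("gene_index out of range")
  idx <- net$inputs[[gene_index]]
  code <- if (length(idx)) sum(state[idx] * 2^(seq_along(idx) - 1L)) else 0L
  net$tables[[gene_index]][code + 1L]
}

# rule outputs for all genes at once
network_outputs <- function(net, state) {
  vapply(seq_len(net$n_genes), function(g) {
    idx <- net$inputs[[g]]
    code <- if (length(idx)) sum(state[idx] * 2^(seq_along(idx) - 1L)) else 0L
    net$tables[[g]][code + 1L]
  }, integer(1))
}

#' Asynchronously settle a Boolean network state
#'
#' Repeatedly picks, uniformly at random, one gene whose rule output disagrees
#' with its current value and flips it to the rule output. Stops at a fixed
#' point (no disagreeing gene) or after `settle_cap` single-gene updates.
#' Uses R's global RNG, so results are reproducible under [set.seed()].
#'
#' @param net A `boolnet` object.
#' @param state 0/1 vector of length `n_genes`.
#' @param settle_cap Maximum number of single-gene updates (default 64).
#' @return A list with `final` (the settled state) and `visited` (the ordered
#'   list of states traversed, starting with the input state).
#' @export
async_settle <- function(net, state, settle_cap = 64L) {
  stopifnot(settle_cap >= 1)
  state <- check_gene_state(net, state)
  visited <- vector("list", settle_cap + 1L)
  visited[[1L]] <- state
  nv <- 1L
  for (i in seq_len(settle_cap)) {
    outs <- network_outputs(net, state)
    disagree <- which(outs != state)
    if (length(disagree) == 0L) break
    g <- disagree[[sample.int(length(disagree), 1L)]]
    state[[g]] <- outs[[g]]
    nv <- nv + 1L
    visited[[nv]] <- state
  }
  list(final = state, visited = visited[seq_len(nv)])
}

#' Apply a single-gene perturbation and settle
#'
#' Flips the expression value of one gene, then lets the network settle via
#' [async_settle()]. This is the environment transition of the reprogramming
#' simulator; it is stochastic through the asynchronous update order.
#'
#' @inheritParams async_settle
#' @param gene_index Gene to flip (1-based).
#' @return A list with `final` (the post-settle state) and `visited` (settle
#'   intermediates, starting from the post-flip state).
#' @export
perturb_step <- function(net, state, gene_index, settle_cap = 64L) {
  state <- check_gene_state(net, state)
  if (gene_index < 1 || gene_index > net$n_genes) stop("gene_index out of range")
  state[[gene_index]] <- 1L - state[[gene_index]]
  async_settle(net, state, settle_cap)
}

#' Enumerate all fixed points of a Boolean network
#'
#' Scans all `2^n_genes` states and returns those where every gene's rule
#' output equals its current value. Supported up to 20 genes (for the
#' 15-gene cardiogenesis-scale networks this is a 32,768-state scan).
#'
#' @param net A `boolnet` object with at most 20 genes.
#' @return A list of 0/1 integer vectors, one per fixed point, in increasing
#'   order of their binary encoding (first gene least significant).
#' @export
find_attractor_states <- function(net) {
  n <- net$n_genes
  if (n > MAX_ENUM_GENES)
    stop("exhaustive fixed-point enumeration unsupported beyond ",
         MAX_ENUM_GENES, " genes")
  codes <- 0:(2^n - 1)
  bits <- vapply(seq_len(n), function(g) bitwAnd(bitwShiftR(codes, g - 1L), 1L),
                 integer(length(codes)))
  bits <- matrix(bits, nrow = length(codes))
  fixed <- rep(TRUE, length(codes))
  for (g in seq_len(n)) {
    idx <- net$inputs[[g]]
    code_g <- if (length(idx)) as.vector(bits[, idx, drop = FALSE] %*% 2^(seq_along(idx) - 1L)) else 0L
    out_g <- net$tables[[g]][code_g + 1L]
    fixed <- fixed & (out_g == bits[, g])
  }
  lapply(which(fixed), function(i) as.integer(bits[i, ]))
}
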