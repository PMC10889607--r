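# Boolean update rules: infix text -> AST -> evaluation / postfix bytecode.
#
# Rule text is infix logic over node names with case-insensitive AND/OR/NOT
# (symbols & | ! also accepted), parentheses, and the constants 0/1.  Node
# names are the remaining token alphabet ([A-Za-z0-9_.-]).

.rule_token_re <- "\\(|\\)|!|&{1,2}|\\|{1,2}|[A-Za-z0-9_.-]+"

.kw_and <- c("and", "&", "&&")
.kw_or <- c("or", "|", "||")
.kw_not <- c("not", "!")

tokenize_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  toks <- regmatches(text, gregexpr(.rule_token_re, text))[[1]]
  residue <- gsub("[[:space:]]", "", gsub(.rule_token_re, " ", text))
  if (nzchar(residue)) {
    stop("invalid character(s) in rule expression '", text, "': '", residue, "'")
  }
  toks
}

#' Parse an infix Boolean rule expression
#'
#' Parses text such as `"(A or B) and not C"` into an abstract syntax tree
#' over the operators `and`, `or`, `not`, node-name variables and the
#' constants 0/1.  Operator keywords are case-insensitive and reserved; any
#' other token is a node name.
#'
#' @param text A single character string with the infix expression.
#' @return A nested list AST with elements `op` (`"var"`, `"const"`, `"not"`,
#'   `"and"`, `"or"`) and operands.
#' @examples
#' ast <- parse_rule_expression("(A or B) and not C")
#' eval_rule(ast, c(A = 1, B = 0, C = 0))
#' @export
parse_rule_expression <- function(text) {
  toks <- tokenize_rule(text)
  if (length(toks) == 0L) stop("empty rule expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]
    pos <<- pos + 1L
    t
  }
  is_kw <- function(tok, kws) !is.na(tok) && tolower(tok) %in% kws

  parse_or <- function() {
    args <- list(parse_and())
    while (is_kw(peek(), .kw_or)) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_unary())
    while (is_kw(peek(), .kw_and)) {
      advance()
      args[[length(args) + 1L]] <- parse_unary()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_unary <- function() {
    tok <- peek()
    if (is.na(tok)) stop("unexpected end of rule expression: '", text, "'")
    if (is_kw(tok, .kw_not)) {
      advance()
      return(list(op = "not", x = parse_unary()))
    }
    if (tok == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) stop("missing closing parenthesis in '", text, "'")
      advance()
      return(e)
    }
    if (tok == ")" || is_kw(tok, c(.kw_and, .kw_or))) {
      stop("unexpected token '", tok, "' in '", text, "'")
    }
    advance()
    if (tok %in% c("0", "1")) return(list(op = "const", value = as.integer(tok)))
    if (tolower(tok) %in% c("true", "false")) {
      return(list(op = "const", value = as.integer(tolower(tok) == "true")))
    }
    list(op = "var", name = tok)
  }

  ast <- parse_or()
  if (pos <= length(toks)) {
    stop("unexpected token '", toks[pos], "' after end of expression '", text, "'")
  }
  ast
}

ast_inputs <- function(ast) {
  switch(ast$op,
    var = ast$name,
    const = character(0),
    not = ast_inputs(ast$x),
    unique(unlist(lapply(ast$args, ast_inputs)))
  )
}

format_ast <- function(ast, wrap = FALSE) {
  out <- switch(ast$op,
    var = ast$name,
    const = as.character(ast$value),
    not = {
      x <- format_ast(ast$x, wrap = TRUE)
      paste0("not ", x)
    },
    and = paste(vapply(ast$args, format_ast, "", wrap = TRUE), collapse = " and "),
    or = paste(vapply(ast$args, format_ast, "", wrap = TRUE), collapse = " or ")
  )
  if (wrap && ast$op %in% c("and", "or", "not")) paste0("(", out, ")") else out
}

#' Evaluate a Boolean rule on a full network state
#'
#' @param rule A `boolean_rule`, or an AST from [parse_rule_expression()].
#' @param state Named 0/1 (or logical) vector covering every node the rule
#'   references.
#' @return Integer 0 or 1.
#' @export
eval_rule <- function(rule, state) {
  ast <- if (inherits(rule, "boolean_rule")) rule$ast else rule
  .eval_ast(ast, state)
}

.eval_ast <- function(a, state) {
  switch(a$op,
    var = {
      v <- state[[a$name]]
      if (is.null(v) || is.na(v)) stop("state does not cover node '", a$name, "'")
      as.integer(as.logical(v))
    },
    const = a$value,
    not = 1L - .eval_ast(a$x, state),
    and = {
      for (x in a$args) if (.eval_ast(x, state) == 0L) return(0L)
      1L
    },
    or = {
      for (x in a$args) if (.eval_ast(x, state) == 1L) return(1L)
      0L
    }
  )
}

#' Construct a Boolean update rule for a node
#'
#' @param target Node identifier the rule updates.
#' @param expression Infix rule text (see [parse_rule_expression()]).
#' @param nodes Optional character vector of declared node names; if given,
#'   any reference to an undeclared node is an error naming that node.
#' @return An object of class `boolean_rule` with fields `target`, `text`,
#'   `ast` and `inputs`.
#' @export
boolean_rule <- function(target, expression, nodes = NULL) {
  stopifnot(is.character(target), length(target) == 1L)
  ast <- parse_rule_expression(expression)
  inputs <- ast_inputs(ast)
  if (!is.null(nodes)) {
    unknown <- setdiff(inputs, nodes)
    if (length(unknown)) {
      stop(
        "rule for '", target, "' references undeclared node(s): ",
        paste(unknown, collapse = ", ")
      )
    }
  }
  structure(
    list(target = target, text = format_ast(ast), ast = ast, inputs = inputs),
    class = "boolean_rule"
  )
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat(x$target, "(t+1) = ", x$text, "\n", sep = "")
  invisible(x)
}

# Postfix bytecode for the C++ engine.  Positive tokens are 1-based node
# indices; negative tokens are operators.
.OP_AND <- -1L
.OP_OR <- -2L
.OP_NOT <- -3L
.OP_ZERO <- -4L
.OP_ONE <- -5L

compile_rule_code <- function(ast, node_index) {
  out <- integer(0)
  emit <- function(a) {
    switch(a$op,
      var = {
        i <- node_index[[a$name]]
        if (is.null(i) || is.na(i)) stop("unknown node '", a$name, "' in rule")
        out[[length(out) + 1L]] <<- as.integer(i)
      },
      const = {
        out[[length(out) + 1L]] <<- if (a$value == 0L) .OP_ZERO else .OP_ONE
      },
      not = {
        emit(a$x)
        out[[length(out) + 1L]] <<- .OP_NOT
      },
      and = {
        emit(a$args[[1L]])
        for (x in a$args[-1L]) {
          emit(x)
          out[[length(out) + 1L]] <<- .OP_AND
        }
      },
      or = {
        emit(a$args[[1L]])
        for (x in a$args[-1L]) {
          emit(x)
          out[[length(out) + 1L]] <<- .OP_OR
        }
      }
    )
  }
  emit(ast)
  out
}
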