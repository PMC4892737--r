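#' Per-pixel color filter expressions
#'
#' Background removal keeps pixels whose color satisfies a logical
#' expression over the channel values, e.g. `"g > b"` — the green value must
#' exceed the blue value, the standard rule for plants on blue or white
#' backgrounds. The grammar supports:
#'
#' * operands: the channel names `r`, `g`, `b` and integer literals
#' * arithmetic: `+ - * /` with the usual precedence (`/` is real-valued)
#' * comparisons: `> >= < <= = !=` (`==` is accepted as a synonym of `=`)
#' * logic: `and`, `or`, `not` (synonyms `& | !`), and parentheses
#'
#' The expression must evaluate to a boolean per pixel. Malformed text,
#' unknown operands, and numeric-only expressions (e.g. `"g + b"`) are
#' rejected with a diagnostic naming the position of the offending token.
#'
#' @param text A filter expression as a single string.
#' @return An object of class `filter_expr`: the parsed expression plus its
#'   source text. Use [filter_apply()] or [color_filter()] to evaluate it.
#' @examples
#' parse_filter("g > b")
#' parse_filter("(g > b) and (g + r > 50)")
#' @export
parse_filter <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("filter expression must be a single string", call. = FALSE)
  toks <- filter_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$src <- text
  node <- fp_or(st)
  if (st$pos <= length(toks$type))
    fp_fail(st, st$pos, "unexpected trailing input")
  if (node$kind != "bool")
    stop(sprintf("filter expression must be boolean, not numeric: \"%s\"", text),
         call. = FALSE)
  structure(list(source = text, expr = node$expr), class = "filter_expr")
}

#' @export
print.filter_expr <- function(x, ...) {
  cat("<filter_expr> ", x$source, "\n", sep = "")
  invisible(x)
}

#' Evaluate a filter expression over an image
#'
#' @param filter A [parse_filter()] result or a string.
#' @param image A [raster_image()].
#' @return Logical `h x w` matrix: `TRUE` where the pixel satisfies the
#'   expression.
#' @export
filter_apply <- function(filter, image) {
  if (is.character(filter)) filter <- parse_filter(filter)
  if (!inherits(filter, "filter_expr"))
    stop("`filter` must be a filter_expr or a string", call. = FALSE)
  assert_raster(image)
  x <- unclass(image)
  env <- list2env(list(
    r = matrix(as.numeric(x[, , 1L]), nrow = dim(x)[1]),
    g = matrix(as.numeric(x[, , 2L]), nrow = dim(x)[1]),
    b = matrix(as.numeric(x[, , 3L]), nrow = dim(x)[1])),
    parent = baseenv())
  keep <- eval(filter$expr, env)
  if (is.logical(keep) && length(keep) == 1L)  # constant expression
    keep <- matrix(keep, dim(x)[1], dim(x)[2])
  keep
}

## --- tokenizer -------------------------------------------------------------

filter_tokenize <- function(text) {
  type <- character(); value <- character(); at <- integer()
  i <- 1L; n <- nchar(text)
  two <- c(">=", "<=", "!=", "==", "&&", "||")
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    rest2 <- substr(text, i, min(i + 1L, n))
    if (rest2 %in% two) {
      op <- if (rest2 == "&&") "and" else if (rest2 == "||") "or" else rest2
      type <- c(type, "op"); value <- c(value, op); at <- c(at, i)
      i <- i + 2L; next
    }
    if (ch %in% c(">", "<", "=", "+", "-", "*", "/", "(", ")")) {
      type <- c(type, "op"); value <- c(value, ch); at <- c(at, i)
      i <- i + 1L; next
    }
    if (ch == "&" || ch == "|" || ch == "!") {
      type <- c(type, "op")
      value <- c(value, c("&" = "and", "|" = "or", "!" = "not")[[ch]])
      at <- c(at, i); i <- i + 1L; next
    }
    if (grepl("^[0-9]$", ch)) {
      m <- regmatches(substr(text, i, n), regexpr("^[0-9]+", substr(text, i, n)))
      type <- c(type, "num"); value <- c(value, m); at <- c(at, i)
      i <- i + nchar(m); next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(text, i, n)))
      lw <- tolower(m)
      if (lw %in% c("and", "or", "not")) {
        type <- c(type, "op"); value <- c(value, lw)
      } else if (lw %in% c("r", "g", "b")) {
        type <- c(type, "chan"); value <- c(value, lw)
      } else {
        stop(sprintf("unknown operand \"%s\" at position %d in \"%s\"", m, i, text),
             call. = FALSE)
      }
      at <- c(at, i); i <- i + nchar(m); next
    }
    stop(sprintf("unexpected character \"%s\" at position %d in \"%s\"", ch, i, text),
         call. = FALSE)
  }
  list(type = type, value = value, at = at)
}

## --- recursive-descent parser ---------------------------------------------
## Each fp_* returns list(expr = <R language object>, kind = "num"|"bool").

fp_fail <- function(st, pos, msg) {
  at <- if (pos <= length(st$toks$at)) st$toks$at[pos] else nchar(st$src) + 1L
  stop(sprintf("parse error at position %d in \"%s\": %s", at, st$src, msg),
       call. = FALSE)
}

fp_peek <- function(st) {
  if (st$pos > length(st$toks$type)) return(NULL)
  list(type = st$toks$type[st$pos], value = st$toks$value[st$pos])
}

fp_take <- function(st) { t <- fp_peek(st); st$pos <- st$pos + 1L; t }

fp_expect_bool <- function(st, node, what) {
  if (node$kind != "bool")
    fp_fail(st, st$pos - 1L, paste0(what, " requires boolean operands"))
  node
}

fp_or <- function(st) {
  left <- fp_and(st)
  repeat {
    t <- fp_peek(st)
    if (is.null(t) || t$value != "or") return(left)
    fp_take(st)
    left <- fp_expect_bool(st, left, "\"or\"")
    right <- fp_expect_bool(st, fp_and(st), "\"or\"")
    left <- list(expr = call("|", left$expr, right$expr), kind = "bool")
  }
}

fp_and <- function(st) {
  left <- fp_not(st)
  repeat {
    t <- fp_peek(st)
    if (is.null(t) || t$value != "and") return(left)
    fp_take(st)
    left <- fp_expect_bool(st, left, "\"and\"")
    right <- fp_expect_bool(st, fp_not(st), "\"and\"")
    left <- list(expr = call("&", left$expr, right$expr), kind = "bool")
  }
}

fp_not <- function(st) {
  t <- fp_peek(st)
  if (!is.null(t) && t$value == "not") {
    fp_take(st)
    inner <- fp_expect_bool(st, fp_not(st), "\"not\"")
    return(list(expr = call("!", inner$expr), kind = "bool"))
  }
  fp_comparison(st)
}

fp_comparison <- function(st) {
  left <- fp_additive(st)
  t <- fp_peek(st)
  if (is.null(t) || !t$value %in% c(">", ">=", "<", "<=", "=", "==", "!="))
    return(left)
  fp_take(st)
  if (left$kind != "num") fp_fail(st, st$pos - 1L, "comparison requires numeric operands")
  right <- fp_additive(st)
  if (right$kind != "num") fp_fail(st, st$pos - 1L, "comparison requires numeric operands")
  op <- switch(t$value, "=" = "==", t$value)
  list(expr = call(op, left$expr, right$expr), kind = "bool")
}

fp_additive <- function(st) {
  left <- fp_multiplicative(st)
  repeat {
    t <- fp_peek(st)
    if (is.null(t) || !t$value %in% c("+", "-")) return(left)
    fp_take(st)
    if (left$kind != "num") fp_fail(st, st$pos - 1L, "arithmetic requires numeric operands")
    right <- fp_multiplicative(st)
    if (right$kind != "num") fp_fail(st, st$pos - 1L, "arithmetic requires numeric operands")
    left <- list(expr = call(t$value, left$expr, right$expr), kind = "num")
  }
}

fp_multiplicative <- function(st) {
  left <- fp_unary(st)
  repeat {
    t <- fp_peek(st)
    if (is.null(t) || !t$value %in% c("*", "/")) return(left)
    fp_take(st)
    if (left$kind != "num") fp_fail(st, st$pos - 1L, "arithmetic requires numeric operands")
    right <- fp_unary(st)
    if (right$kind != "num") fp_fail(st, st$pos - 1L, "arithmetic requires numeric operands")
    left <- list(expr = call(t$value, left$expr, right$expr), kind = "num")
  }
}

fp_unary <- function(st) {
  t <- fp_peek(st)
  if (!is.null(t) && t$value == "-") {
    fp_take(st)
    inner <- fp_unary(st)
    if (inner$kind != "num") fp_fail(st, st$pos - 1L, "unary minus requires a numeric operand")
    return(list(expr = call("-", inner$expr), kind = "num"))
  }
  fp_primary(st)
}

fp_primary <- function(st) {
  t <- fp_take(st)
  if (is.null(t)) fp_fail(st, st$pos, "unexpected end of expression")
  if (t$type == "num") return(list(expr = as.numeric(t$value), kind = "num"))
  if (t$type == "chan") return(list(expr = as.name(t$value), kind = "num"))
  if (t$value == "(") {
    inner <- fp_or(st)
    t2 <- fp_take(st)
    if (is.null(t2) || t2$value != ")") fp_fail(st, st$pos - 1L, "expected \")\"")
    return(list(expr = call("(", inner$expr), kind = inner$kind))
  }
  fp_fail(st, st$pos - 1L, sprintf("unexpected token \"%s\"", t$value))
}
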