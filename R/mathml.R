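# MathML <-> R expression translation for kinetic laws.
#
# Supported subset: <ci>, <cn> (real/integer/e-notation), and <apply> with
# plus, minus, times, divide, power. Anything else (piecewise, functions,
# logicals) is rejected loudly: the toolkit's rate laws are rational
# Hill/mass-action expressions and silent acceptance of unsupported
# semantics would corrupt the ODE right-hand side.

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  switch(name,
    math = {
      kids <- xml2::xml_children(node)
      abort_if(length(kids) != 1L,
               "kinetic-law <math> must contain exactly one expression")
      mathml_to_expr(kids[[1]])
    },
    ci = as.name(trimws(xml2::xml_text(node))),
    cn = parse_cn(node),
    apply = parse_apply(node),
    stop("unsupported MathML construct <", name, ">", call. = FALSE)
  )
}

parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  txt <- trimws(xml2::xml_text(node))
  if (!is.na(type) && type == "e-notation") {
    # <cn type="e-notation"> mantissa <sep/> exponent </cn>
    parts <- strsplit(txt, "[[:space:]]+")[[1]]
    abort_if(length(parts) != 2L, "malformed e-notation <cn>")
    return(as.numeric(parts[1]) * 10^as.numeric(parts[2]))
  }
  val <- suppressWarnings(as.numeric(txt))
  abort_if(is.na(val), "non-numeric <cn> content: ", txt)
  val
}

parse_apply <- function(node) {
  kids <- xml2::xml_children(node)
  abort_if(length(kids) < 2L, "<apply> needs an operator and operands")
  op <- xml2::xml_name(kids[[1]])
  args <- lapply(kids[-1], mathml_to_expr)
  rop <- switch(op,
    plus = "+", minus = "-", times = "*", divide = "/", power = "^",
    stop("unsupported MathML operator <", op, ">", call. = FALSE)
  )
  if (rop == "-" && length(args) == 1L) return(call("-", args[[1]]))
  abort_if(rop %in% c("/", "^") && length(args) != 2L,
           "<", op, "> takes exactly two operands")
  abort_if(rop == "-" && length(args) > 2L,
           "<minus> takes one or two operands")
  if (length(args) == 1L) return(args[[1]])
  # n-ary plus/times fold left, matching R's association
  Reduce(function(a, b) call(rop, a, b), args)
}

expr_to_mathml_string <- function(expr, indent = "  ") {
  paste0(
    "<math xmlns=\"", MATHML_NS, "\">",
    expr_node_string(expr),
    "</math>"
  )
}

expr_node_string <- function(e) {
  if (is.numeric(e)) {
    v <- as.numeric(e)
    if (is.finite(v) && v == floor(v) && abs(v) < 1e15) {
      return(paste0("<cn type=\"integer\">", format(v, scientific = FALSE),
                    "</cn>"))
    }
    return(paste0("<cn type=\"real\">", fmt_num(v), "</cn>"))
  }
  if (is.name(e)) {
    return(paste0("<ci> ", as.character(e), " </ci>"))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(expr_node_string(e[[2]]))
    tag <- switch(op,
      "+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
      "^" = "power",
      stop("cannot serialise operator '", op, "' to MathML", call. = FALSE)
    )
    args <- as.list(e)[-1]
    paste0("<apply><", tag, "/>",
           paste(vapply(args, expr_node_string, character(1)), collapse = ""),
           "</apply>")
  } else {
    stop("cannot serialise ", class(e)[1], " to MathML", call. = FALSE)
  }
}

# drop redundant `(` calls: MathML is fully parenthesised by structure, so
# expressions are canonicalised without them at document construction
strip_parens <- function(e) {
  if (is.call(e)) {
    if (identical(e[[1]], as.name("("))) return(strip_parens(e[[2]]))
    for (i in seq_along(e)[-1]) e[[i]] <- strip_parens(e[[i]])
  }
  e
}

# all symbols referenced by a kinetic-law expression
expr_symbols <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) {
    return(unique(unlist(lapply(as.list(e)[-1], expr_symbols))))
  }
  character(0)
}

# evaluate an expression tree against a named list/environment of values
eval_expr <- function(e, values) {
  eval(e, envir = values)
}
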