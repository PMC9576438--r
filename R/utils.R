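# shared internal helpers

# locale-independent (byte order) sort: all node/entity orderings in the
# package must be reproducible across platforms
lex_sort <- function(x) sort(x, method = "radix")

# number formatting used by every file writer so reruns are byte-identical
fmt_num <- function(x) sprintf("%.17g", x)

stop_rwrdr <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
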