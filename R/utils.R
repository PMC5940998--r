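# Internal helpers shared across modules.

# Byte-wise (ordinal) sort, locale independent.  "alphabetical" in the RInChI
# sense means plain ASCII byte order, so radix sort is used everywhere a layer
# or pool is ordered.
ord_sort <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

# TRUE if a < b in byte order (strict).
ord_lt <- function(a, b) {
  if (identical(a, b)) return(FALSE)
  identical(ord_sort(c(a, b))[1L], a)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rxnid <- function(..., class = "rxnid_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
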