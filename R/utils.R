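# Run code with a local RNG state so generators are pure in (spec, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Delimiter by extension: .tsv/.tab -> tab, otherwise comma.
delim_for <- function(path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                    progress = FALSE)
}

write_delim_auto <- function(x, path) {
  readr::write_delim(x, path, delim = delim_for(path))
  invisible(path)
}
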