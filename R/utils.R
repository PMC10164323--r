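# internal helpers shared across modules

# atomic numbers for SMARTS [#n] emission; covers organic-subset elements
# plus the halogens and a few hetero elements common in odorants
.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53, Se = 34
)

atomic_number <- function(symbol) {
  z <- .atomic_numbers[symbol]
  if (anyNA(z)) {
    abort(paste0("unsupported element(s): ",
                 paste(unique(symbol[is.na(z)]), collapse = ", ")))
  }
  unname(z)
}

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# normalize a vector/list of descriptor strings: trim, drop empties, unique
normalize_descriptors <- function(x) {
  x <- trimws(as.character(x))
  unique(x[nzchar(x)])
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single number in [0, 1]"))
  }
}

# argmax set with a small relative tolerance against float jitter in sums
argmax_set <- function(x, tol = 1e-9) {
  m <- max(x)
  which(x >= m - tol * max(1, abs(m)))
}
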