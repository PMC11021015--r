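# Variant library construction: the saturation set of protein-level single
# substitutions over a set of mutagenized regions, plus the tiling used by
# tile-based sequencing.

#' Generate a saturation variant library over mutagenized regions
#'
#' For every position covered by `regions`, emits the 19 missense variants,
#' one nonsense variant (`*`) and one synonymous variant (alt equal to wild
#' type), i.e. 21 protein-level variants per position. This mirrors regional
#' saturation mutagenesis libraries used in deep mutational scans; position 1
#' (the initiator methionine) is conventionally excluded, so regions must
#' start at 2 or later.
#'
#' @param protein_sequence Either a single string or a character vector of
#'   one-letter amino acids; length defines the protein length.
#' @param regions A list of length-2 integer vectors `c(start, end)`
#'   (inclusive, 1-based). Regions must be disjoint and lie within
#'   `[2, protein_length]`.
#' @return A tibble with columns `position`, `wt_aa`, `alt_aa`, `var_class`
#'   (`missense`/`nonsense`/`synonymous`), ordered by `(position, alt_aa)`
#'   with `*` sorting last within a position.
#' @examples
#' lib <- generate_library("MKTAYIAKQR", list(c(2, 10)))
#' nrow(lib) # 9 positions x 21
#' @export
generate_library <- function(protein_sequence, regions) {
  seq_vec <- .as_aa_vector(protein_sequence)
  n <- length(seq_vec)
  if (n < 2L) stop("protein sequence must have length >= 2")
  regions <- .validate_regions(regions, n)

  positions <- sort(unique(unlist(lapply(regions, function(r) seq(r[1], r[2])))))
  wt <- seq_vec[positions]
  alts <- c(AA_ALPHABET, "*")
  out <- tibble::tibble(
    position = rep(positions, each = length(alts)),
    wt_aa = rep(wt, each = length(alts)),
    alt_aa = rep(alts, times = length(positions))
  )
  out$var_class <- dplyr::case_when(
    out$alt_aa == "*" ~ "nonsense",
    out$alt_aa == out$wt_aa ~ "synonymous",
    TRUE ~ "missense"
  )
  # deterministic ordering: positions ascending, alt A..Y then '*'
  out <- out[order(out$position, match(out$alt_aa, alts)), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Assign library positions to sequencing tiles
#'
#' Splits each mutagenized region into consecutive tiles of near-equal length
#' (short amplicons so both strands of each tile can be read). Tiles are
#' numbered consecutively across regions. With the default three regions and
#' a 5/5/4 split this reproduces a 14-tile design over a 465-residue protein.
#'
#' @param regions List of `c(start, end)` intervals as in
#'   [generate_library()].
#' @param tiles_per_region Integer vector, one entry per region.
#' @return A tibble with columns `position`, `tile`.
#' @export
tile_map <- function(regions, tiles_per_region) {
  regions <- .validate_regions(regions, Inf)
  if (length(tiles_per_region) != length(regions)) {
    stop("tiles_per_region must have one entry per region")
  }
  tile0 <- 0L
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    pos <- seq(regions[[i]][1], regions[[i]][2])
    k <- tiles_per_region[i]
    if (k < 1L || k > length(pos)) {
      stop("region ", i, " cannot be split into ", k, " tiles")
    }
    cut_idx <- ceiling(seq_along(pos) / (length(pos) / k))
    out[[i]] <- tibble::tibble(position = pos, tile = tile0 + as.integer(cut_idx))
    tile0 <- tile0 + k
  }
  dplyr::bind_rows(out)
}

#' Draw a random protein sequence
#'
#' Used by tests and examples; the pipeline never needs the real sequence of
#' the assayed protein, only a sequence of the right length.
#'
#' @param length Number of residues (the first is fixed to `M`).
#' @param seed Integer seed.
#' @return A character vector of one-letter codes.
#' @export
random_protein_sequence <- function(length, seed = 1L) {
  stopifnot(length >= 2)
  withr_seed <- .local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  c("M", sample(AA_ALPHABET, length - 1L, replace = TRUE))
}

#' Default mutagenized regions
#'
#' Three regional libraries; at the default length of 465 residues they span
#' 2-171, 172-337, and 338-465. Other protein lengths scale the two interior
#' breakpoints proportionally.
#'
#' @param protein_length Protein length.
#' @return List of `c(start, end)` integer vectors.
#' @export
default_regions <- function(protein_length = 465L) {
  n <- as.integer(protein_length)
  b1 <- as.integer(round(n * 171 / 465))
  b2 <- as.integer(round(n * 337 / 465))
  list(c(2L, b1), c(b1 + 1L, b2), c(b2 + 1L, n))
}

# ---- internal helpers -------------------------------------------------------

.as_aa_vector <- function(protein_sequence) {
  if (length(protein_sequence) == 1L && nchar(protein_sequence) > 1L) {
    protein_sequence <- strsplit(protein_sequence, "")[[1]]
  }
  seq_vec <- toupper(as.character(protein_sequence))
  bad <- setdiff(unique(seq_vec), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("sequence contains non-standard residues: ", paste(bad, collapse = ", "))
  }
  seq_vec
}

.validate_regions <- function(regions, protein_length) {
  if (!is.list(regions) || length(regions) == 0L) {
    stop("regions must be a non-empty list of c(start, end) intervals")
  }
  regions <- lapply(regions, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop("each region must be c(start, end) with start <= end")
    }
    if (r[1] < 2L) stop("regions must start at position 2 or later")
    if (r[2] > protein_length) stop("region end ", r[2], " exceeds protein length")
    r
  })
  ord <- order(vapply(regions, `[`, 1L, 1L))
  regions <- regions[ord]
  if (length(regions) > 1L) {
    for (i in seq_len(length(regions) - 1L)) {
      if (regions[[i + 1L]][1] <= regions[[i]][2]) {
        stop(
          "regions overlap: [", regions[[i]][1], ",", regions[[i]][2], "] and [",
          regions[[i + 1L]][1], ",", regions[[i + 1L]][2], "]"
        )
      }
    }
  }
  regions
}

# Save and restore the RNG state around a locally seeded computation, so that
# package functions are reproducible without clobbering the caller's stream.
.local_seed <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Deterministic sub-seed derivation: one master seed spawns independent
# per-tile / per-replicate streams. Kept below 2^31 - 1.
.derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 16807 + 11) %% 2147483647
  }
  as.integer(h)
}
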