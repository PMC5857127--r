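#' Microbial assignment configuration (step 7)
#'
#' @param min_identity Minimum alignment identity.
#' @param min_aligned_fraction Minimum aligned fraction of the read
#'   (full-read anchored alignments always satisfy it).
#' @return A list of class `rop_microbial_config`.
#' @export
microbial_config <- function(min_identity = 0.9,
                             min_aligned_fraction = 0.8) {
  structure(list(min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction),
            class = "rop_microbial_config")
}

TAXON_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                 "species")

# lowest common ancestor of semicolon paths; "" when even domains differ
lca_path <- function(paths) {
  parts <- strsplit(paths, ";", fixed = TRUE)
  n <- min(lengths(parts))
  keep <- 0
  for (i in seq_len(n)) {
    lev <- vapply(parts, `[[`, "", i)
    if (length(unique(lev)) == 1) keep <- i else break
  }
  if (keep == 0) return("")
  paste(parts[[1]][seq_len(keep)], collapse = ";")
}

#' Assign remaining unmapped reads to microbial genomes
#'
#' Each read goes to its best-hit genome (identity at least
#' `config$min_identity` over the read); when the best hit is tied across
#' genomes of different taxa the read is assigned to the lowest common
#' ancestor taxon and counts at that rank only.  The taxonomic profile
#' aggregates counts up the taxon paths.
#'
#' @param reads Read tibble.
#' @param microbial_index `rop_index` over the microbial genomes.
#' @param taxa Taxon map tibble (`genome`, `taxon_path`).
#' @param config Microbial configuration.
#' @param aligner Aligner configuration.
#' @return List with `assignments` (read_id, genome or `NA`, `lca` path or
#'   `NA`, plus alignment detail), `profile` (tibble rank, taxon, count,
#'   relative_abundance), `microbial_load`.
#' @export
assign_microbial <- function(reads, microbial_index, taxa,
                             config = microbial_config(),
                             aligner = aligner_config()) {
  if (length(microbial_index$names) == 0) stop("empty microbial reference set")
  empty_assign <- tibble::tibble(read_id = character(), genome = character(),
                                 lca = character(), ref_start = integer(),
                                 ref_end = integer(),
                                 edit_distance = integer())
  if (nrow(reads) == 0) {
    return(list(assignments = empty_assign,
                profile = tibble::tibble(rank = character(),
                                         taxon = character(),
                                         count = integer(),
                                         relative_abundance = numeric()),
                microbial_load = 0L))
  }
  budget <- floor((1 - config$min_identity) * max(nchar(reads$sequence)))
  hits <- align_reads(reads, microbial_index, budget, aligner)
  hits <- hits[hits$edit_distance <=
                 (1 - config$min_identity) * hits$read_length, ]
  if (!nrow(hits)) {
    return(list(assignments = empty_assign,
                profile = tibble::tibble(rank = character(),
                                         taxon = character(),
                                         count = integer(),
                                         relative_abundance = numeric()),
                microbial_load = 0L))
  }
  path_of <- stats::setNames(taxa$taxon_path, taxa$genome)
  assignments <- hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$edit_distance == min(.data$edit_distance)) |>
    dplyr::group_modify(function(d, key) {
      genomes <- unique(d$ref_id)
      if (length(genomes) == 1) {
        tibble::tibble(genome = genomes, lca = NA_character_,
                       ref_start = d$ref_start[1], ref_end = d$ref_end[1],
                       edit_distance = d$edit_distance[1])
      } else {
        lca <- lca_path(unname(path_of[genomes]))
        tibble::tibble(genome = NA_character_,
                       lca = if (nzchar(lca)) lca else NA_character_,
                       ref_start = NA_integer_, ref_end = NA_integer_,
                       edit_distance = d$edit_distance[1])
      }
    }) |>
    dplyr::ungroup()
  # drop reads whose tie has no common ancestor at any rank
  assignments <- assignments[!(is.na(assignments$genome) &
                                 is.na(assignments$lca)), ]
  paths <- ifelse(is.na(assignments$genome),
                  assignments$lca, unname(path_of[assignments$genome]))
  prof <- list()
  for (i in seq_along(paths)) {
    p <- strsplit(paths[i], ";", fixed = TRUE)[[1]]
    prof[[i]] <- tibble::tibble(rank = TAXON_RANKS[seq_along(p)], taxon = p)
  }
  profile <- dplyr::bind_rows(prof) |>
    dplyr::count(.data$rank, .data$taxon, name = "count") |>
    dplyr::group_by(.data$rank) |>
    dplyr::mutate(relative_abundance = 100 * .data$count /
                    sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(rank = factor(.data$rank, levels = TAXON_RANKS)) |>
    dplyr::arrange(.data$rank, .data$taxon) |>
    dplyr::mutate(rank = as.character(.data$rank))
  list(assignments = assignments, profile = profile,
       microbial_load = nrow(assignments))
}

#' Per-base coverage of a microbial genome
#'
#' Reads assigned at a lowest-common-ancestor taxon carry no placement and
#' do not contribute.
#'
#' @param assignments Assignment tibble from [assign_microbial()].
#' @param genome_name Genome to profile.
#' @param genome_length Genome length in bases.
#' @return List with `depth` (integer vector) and `breadth` (fraction of
#'   positions covered at least once).
#' @export
coverage_profile <- function(assignments, genome_name, genome_length) {
  depth <- integer(genome_length)
  a <- assignments[!is.na(assignments$genome) &
                     assignments$genome == genome_name, ]
  for (i in seq_len(nrow(a))) {
    lo <- a$ref_start[i] + 1
    hi <- min(a$ref_end[i], genome_length)
    depth[lo:hi] <- depth[lo:hi] + 1L
  }
  list(depth = depth, breadth = mean(depth > 0))
}
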