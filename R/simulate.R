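# Coalescent branches for n lineages under a piecewise-constant population
# history: coalescence rate j(j-1)/2 up to time tau, multiplied by g beyond
# (g > 1 means the population was g-fold smaller before tau - a recent
# expansion, producing star-like genealogies). g = 1 is the standard
# constant-size coalescent.
.coal_branches_growth <- function(n, g = 1, tau = Inf) {
  sets <- as.list(seq_len(n))
  len <- numeric(n)
  out_sets <- vector("list", max(0L, 2L * n - 2L))
  out_len <- numeric(max(0L, 2L * n - 2L))
  k <- 0L
  j <- n
  t_now <- 0
  while (j > 1L) {
    e <- stats::rexp(1L, rate = j * (j - 1) / 2)
    dt <- if (t_now >= tau) e / g
          else if (e <= tau - t_now) e
          else (tau - t_now) + (e - (tau - t_now)) / g
    t_now <- t_now + dt
    len <- len + dt
    pr <- sample.int(j, 2L)
    for (p in pr) {
      k <- k + 1L
      out_sets[[k]] <- sets[[p]]
      out_len[k] <- len[p]
    }
    merged <- c(sets[[pr[1L]]], sets[[pr[2L]]])
    keep <- setdiff(seq_len(j), pr)
    sets <- c(sets[keep], list(merged))
    len <- c(len[keep], 0)
    j <- j - 1L
  }
  list(sets = out_sets, len = out_len)
}

#' Simulate one symbiont species' infrapopulation sample
#'
#' Two-phase coalescent emulating vertically transmitted infrapopulations.
#' Within each host bird, the `m` sampled mites descend from at most `f`
#' founder lineages (uniform random assignment; founders are distinct when
#' `f >= m`) whose within-bird coalescence is treated as instantaneous -
#' the founder-event kin structure that makes mites of one bird share
#' haplotypes. The founder lineages of all birds then follow a neutral
#' coalescent: constant-size in `equilibrium` mode, or with all branch
#' segments older than `tau` compressed `g`-fold in `expansion` mode (a
#' recent g-fold population expansion, yielding star-like genealogies and
#' low R2). Mutations are dropped Poisson with per-branch mean
#' length x theta/2 x L and placed at distinct uniform sites (quasi-
#' infinite sites on L positions; no back-mutation).
#'
#' @param species species label.
#' @param M median infrapopulation size recorded for the species (> 0);
#'   carried into the loads table, not used by the genealogy itself.
#' @param B number of host birds sampled.
#' @param m mites sampled per bird.
#' @param f founder lineages per bird (`1` = full within-bird identity).
#' @param theta scaled mutation rate per site; the equilibrium expectation
#'   of nucleotide diversity when `f = m`.
#' @param L alignment length in sites (default 507).
#' @param mode `"equilibrium"` or `"expansion"`.
#' @param g expansion factor (> 1; only used in expansion mode).
#' @param tau expansion time in coalescent units (expansion mode).
#' @return list with `seqs` (named character vector of sequences) and
#'   `metadata` (data.frame: sample_id, species, bird_id, locality, source).
#' @export
simulate_species <- function(species, M, B, m, f, theta, L = 507L,
                             mode = c("equilibrium", "expansion"),
                             g = 30, tau = 0.05) {
  mode <- match.arg(mode)
  stopifnot(M > 0, B >= 1L, m >= 1L, f >= 1L, theta >= 0, L >= 1L)
  if (mode == "expansion" && g <= 1)
    stop("expansion mode needs growth factor g > 1", call. = FALSE)
  # founder assignment: mite -> within-bird founder index
  founder_of <- matrix(0L, B, m)
  for (b in seq_len(B))
    founder_of[b, ] <- if (f >= m) sample.int(f, m)
                       else sample.int(f, m, replace = TRUE)
  # global lineage per used (bird, founder) pair
  used <- unique(data.frame(bird = rep(seq_len(B), each = m),
                            founder = as.vector(t(founder_of))))
  K <- nrow(used)
  lineage_id <- function(b, fo) match(paste(b, fo), paste(used$bird, used$founder))

  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  lin_seq <- matrix(rep(root, each = K), nrow = K)   # K x L
  if (K > 1L && theta > 0) {
    br <- if (mode == "expansion")
      .coal_branches_growth(K, g = g, tau = tau)
    else .coal_branches_growth(K)
    n_mut <- stats::rpois(length(br$len), br$len * theta / 2 * L)
    total <- sum(n_mut)
    if (total > L)
      stop("more mutations (", total, ") than sites (", L,
           "): increase L or decrease theta", call. = FALSE)
    if (total > 0L) {
      pos <- sample.int(L, total)        # distinct positions
      p <- 0L
      for (e in seq_along(n_mut)) {
        if (n_mut[e] == 0L) next
        for (mu in seq_len(n_mut[e])) {
          p <- p + 1L
          site <- pos[p]
          derived <- sample(setdiff(c("A", "C", "G", "T"), root[site]), 1L)
          lin_seq[br$sets[[e]], site] <- derived
        }
      }
    }
  }
  ids <- character(B * m)
  birds <- character(B * m)
  seqs <- character(B * m)
  k <- 0L
  for (b in seq_len(B)) {
    for (mi in seq_len(m)) {
      k <- k + 1L
      ids[k] <- sprintf("%s_b%02d_m%d", species, b, mi)
      birds[k] <- sprintf("%s_b%02d", species, b)
      seqs[k] <- paste(lin_seq[lineage_id(b, founder_of[b, mi]), ],
                       collapse = "")
    }
  }
  names(seqs) <- ids
  list(seqs = seqs,
       metadata = data.frame(sample_id = ids, species = species,
                             bird_id = birds, locality = "sim",
                             source = "multi_per_bird",
                             stringsAsFactors = FALSE))
}

#' Default multi-species simulation preset
#'
#' A 17-species host-symbiont system in the image of a passerine feather
#' mite survey: median loads log-spaced over one order of magnitude
#' (5 to 50 mites per bird), 6-12 birds per species with 5 mites sampled
#' from each, strong within-bird kin structure (2 founder lineages per
#' bird), species diversity scaling as theta = theta0 * M^beta, and two
#' recent-expansion (star-like) species. The defaults put the preset's
#' realised diversity in the few-per-mille to few-percent per-site range
#' typical of COI surveys.
#'
#' @param n_species number of species (default 17).
#' @param theta0,beta diversity-load scaling theta = theta0 * M^beta.
#' @param expansion_species indices of species simulated in expansion mode.
#' @param g,tau expansion parameters (see [simulate_species()]).
#' @param L alignment length.
#' @return A config list (`species` data.frame + `L`) for
#'   [simulate_system()].
#' @export
default_preset <- function(n_species = 17L, theta0 = 2.8e-4, beta = 1.3,
                           expansion_species = c(9L, 12L), g = 30,
                           tau = 0.05, L = 507L) {
  M <- round(exp(seq(log(5), log(50), length.out = n_species)), 1)
  mode <- rep("equilibrium", n_species)
  mode[intersect(expansion_species, seq_len(n_species))] <- "expansion"
  list(species = data.frame(
         species = sprintf("sp%02d", seq_len(n_species)),
         M = M,
         B = 6L + (seq_len(n_species) - 1L) %% 7L,
         m = 5L,
         f = 2L,
         theta = theta0 * M^beta,
         mode = mode,
         g = g, tau = tau,
         stringsAsFactors = FALSE),
       L = as.integer(L))
}

#' Simulate a full host-symbiont system
#'
#' Assembles every species of a config into one alignment + metadata +
#' loads fixture, with a truth record sufficient for parameter-recovery
#' tests. Each species draws under its own seed sub-stream, so the system
#' is reproducible and adding a species leaves the others' data unchanged.
#'
#' @param config a config list as returned by [default_preset()].
#' @param seed master seed (integer).
#' @return An object of class `simulated_system`: list with `datasets`
#'   (named list of [species_dataset()]), `alignment`, `metadata`, `loads`,
#'   `truth` (per-species data.frame with theta and mode) and `seed`.
#' @export
simulate_system <- function(config = default_preset(), seed = 1L) {
  sp <- config$species
  stopifnot(is.data.frame(sp), nrow(sp) >= 1L)
  seqs <- character(0)
  md <- list()
  for (r in seq_len(nrow(sp))) {
    sim <- with_seed(substream_seed(seed, 0L, sp$species[r]),
      simulate_species(sp$species[r], sp$M[r], sp$B[r], sp$m[r], sp$f[r],
                       sp$theta[r], L = config$L, mode = sp$mode[r],
                       g = sp$g[r], tau = sp$tau[r]))
    seqs <- c(seqs, sim$seqs)
    md[[r]] <- sim$metadata
  }
  metadata <- do.call(rbind, md)
  aln <- alignment(names(seqs), unname(seqs))
  loads <- stats::setNames(sp$M, sp$species)
  datasets <- suppressWarnings(build_species_datasets(aln, metadata, loads))
  truth <- sp[, c("species", "M", "B", "m", "f", "theta", "mode")]
  structure(list(datasets = datasets, alignment = aln, metadata = metadata,
                 loads = loads, truth = truth, config = config, seed = seed),
            class = "simulated_system")
}

#' @export
print.simulated_system <- function(x, ...) {
  cat(sprintf("simulated system: %d species, %d sequences x %d bp (seed %d)\n",
              nrow(x$truth), length(x$alignment$ids), x$alignment$L, x$seed))
  invisible(x)
}

#' Write a simulated system to fixture files
#'
#' Emits `alignment.fasta`, `metadata.tsv`, `loads.tsv` and `truth.json`
#' into `out_dir`; files are a function of the system object only, so the
#' same seed yields byte-identical fixtures.
#'
#' @param system a [simulate_system()] result.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(system, out_dir) {
  stopifnot(inherits(system, "simulated_system"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- c(alignment = file.path(out_dir, "alignment.fasta"),
             metadata = file.path(out_dir, "metadata.tsv"),
             loads = file.path(out_dir, "loads.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_alignment(system$alignment, paths["alignment"])
  utils::write.table(system$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(species = names(system$loads),
                                median_load = as.numeric(system$loads)),
                     paths["loads"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(seed = system$seed, species = system$truth),
                       paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
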