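# Genetic-algorithm search over binary subimage subsets. Chromosomes are
# 0/1 vectors over the unfolded grid; fitness is the LOOCV RMSECV of a
# PLS1 model on the pooled histogram features of the selected subimages
# (lower is better). Selection is roulette-wheel on 1/RMSECV, with
# single-point crossover, per-gene mutation, elitism, and a repair step
# that enforces the 1..Nim selected-subimage constraint.

#' Genetic-algorithm configuration
#'
#' Defaults mirror the reported chromatogram run: 100 individuals, 100
#' generations, mutation probability 0.05 (per gene), crossover
#' probability 0.65, elitism 0.10, best of 10 restarts.
#'
#' @param popSize population size (>= 2).
#' @param generations number of generations.
#' @param elitismRate fraction of the population carried over unchanged.
#' @param crossoverRate probability that a parent pair is recombined.
#' @param mutationRate per-gene flip probability.
#' @param nim maximum number of selected subimages; \code{NA} means the
#'   whole grid.
#' @param nRestarts independent restarts for [runRestarts()].
#' @param nLV fixed latent-variable count used inside fitness; \code{NA}
#'   selects by minimum RMSECV up to \code{lvMax} per chromosome.
#' @param lvMax LV search ceiling when \code{nLV} is \code{NA}.
#' @param channels color channels for the histogram features.
#' @return A \linkS4class{GAConfig}.
#' @export
gaConfig <- function(popSize = 100, generations = 100,
                     elitismRate = 0.10, crossoverRate = 0.65,
                     mutationRate = 0.05, nim = NA, nRestarts = 10,
                     nLV = 2, lvMax = 5, channels = c("R", "G", "B")) {
    new("GAConfig", popSize = as.integer(popSize),
        generations = as.integer(generations),
        elitismRate = elitismRate, crossoverRate = crossoverRate,
        mutationRate = mutationRate, nim = as.integer(nim),
        nRestarts = as.integer(nRestarts), nLV = as.integer(nLV),
        lvMax = as.integer(lvMax), channels = channels)
}

#' Random initial population
#'
#' Each chromosome draws its number of selected subimages uniformly from
#' \code{1..nim} and places them uniformly without replacement. Uses the
#' current RNG state; seed with \code{set.seed()} (or let [evolve()] do
#' it) for reproducibility.
#'
#' @param config a \linkS4class{GAConfig}.
#' @param nGenes chromosome length (\code{roi1 * roi2}).
#' @return integer 0/1 matrix, \code{popSize x nGenes}.
#' @export
initPopulation <- function(config, nGenes) {
    nim <- effectiveNim(config, nGenes)
    P <- matrix(0L, config@popSize, nGenes)
    for (i in seq_len(config@popSize)) {
        k <- sample.int(nim, 1L)
        P[i, sample.int(nGenes, k)] <- 1L
    }
    P
}

effectiveNim <- function(config, nGenes) {
    nim <- if (is.na(config@nim)) nGenes else config@nim
    if (nim > nGenes)
        stop("nim (", nim, ") exceeds the number of subimages (",
             nGenes, ")")
    nim
}

#' Fitness of a chromosome: LOOCV RMSECV of its pooled-histogram model
#'
#' Builds the feature matrix for the selected subimages from a per-cell
#' histogram cache (see [cellHistogramCache()]) and cross-validates a PLS1
#' model. A degenerate feature matrix (no covariance with y) yields an
#' \code{Inf} sentinel rather than an error, so the search can continue.
#'
#' @param genes integer 0/1 vector.
#' @param cache array from [cellHistogramCache()].
#' @param y numeric response.
#' @param config a \linkS4class{GAConfig}; supplies the LV rule.
#' @return RMSECV in response units (\code{Inf} for degenerate subsets).
#' @export
chromosomeFitness <- function(genes, cache, y, config) {
    sel <- which(genes == 1L)
    if (length(sel) == 0L)
        stop("invalid chromosome: no subimage selected")
    X <- pooledFeatures(cache, sel)
    lv_cap <- min(nrow(X) - 2L, ncol(X))
    tryCatch({
        if (!is.na(config@nLV))
            loocv(X, y, min(config@nLV, lv_cap))$rmsecv
        else
            selectLV(X, y, min(config@lvMax, lv_cap))$rmsecvChosen
    }, error = function(e) Inf)
}

#' Roulette-wheel parent selection
#'
#' Selection probability proportional to \code{1/rmsecv} (the
#' minimization transform); chromosomes with non-finite fitness are
#' excluded from the wheel. Two draws with replacement, so a parent can
#' be picked twice.
#'
#' @param fitness numeric vector of RMSECV values.
#' @return integer vector of two population indices.
#' @export
rouletteSelect <- function(fitness) {
    ok <- which(is.finite(fitness) & fitness > 0)
    if (length(ok) == 0L)
        return(sample.int(length(fitness), 2L, replace = TRUE))
    if (length(ok) == 1L) return(c(ok, ok))
    w <- 1 / fitness[ok]
    ok[sample.int(length(ok), 2L, replace = TRUE, prob = w)]
}

#' Single-point crossover
#'
#' With probability \code{rate}, a cut point is drawn uniformly in
#' \code{1..L-1} and gene suffixes are swapped; otherwise the parents are
#' copied unchanged.
#'
#' @param a,b integer 0/1 vectors of equal length.
#' @param rate crossover probability.
#' @return list of two offspring vectors.
#' @export
crossoverSinglePoint <- function(a, b, rate = 0.65) {
    stopifnot(length(a) == length(b))
    L <- length(a)
    if (L >= 2L && runif(1) < rate) {
        cut <- sample.int(L - 1L, 1L)
        list(c(a[seq_len(cut)], b[(cut + 1L):L]),
             c(b[seq_len(cut)], a[(cut + 1L):L]))
    } else list(a, b)
}

#' Per-gene mutation
#'
#' Each gene flips independently with probability \code{rate}.
#'
#' @param genes integer 0/1 vector.
#' @param rate per-gene flip probability.
#' @return mutated 0/1 vector.
#' @export
mutateGenes <- function(genes, rate) {
    flip <- runif(length(genes)) < rate
    ifelse(flip, 1L - genes, genes)
}

#' Repair a chromosome to satisfy the 1..Nim constraint
#'
#' An all-zero chromosome gains one uniformly random gene; a chromosome
#' with more than \code{nim} ones has randomly chosen ones cleared until
#' exactly \code{nim} remain (retained ones are always a subset of the
#' original selection).
#'
#' @param genes integer 0/1 vector.
#' @param nim maximum number of ones.
#' @return repaired 0/1 vector.
#' @export
repairChromosome <- function(genes, nim) {
    ones <- which(genes == 1L)
    if (length(ones) == 0L) {
        genes[sample.int(length(genes), 1L)] <- 1L
    } else if (length(ones) > nim) {
        drop <- sample(ones, length(ones) - nim)
        genes[drop] <- 0L
    }
    genes
}

#' Run one genetic-algorithm search
#'
#' Evolves a population for \code{generations} cycles: the top
#' \code{ceil(elitismRate * popSize)} chromosomes are carried over
#' unchanged, the remainder is filled by roulette selection, single-point
#' crossover, mutation and repair. Fitness values are memoized on the gene
#' pattern (fitness is a pure function of it), which is what makes
#' desk-scale runs affordable. Fully reproducible from \code{seed}.
#'
#' @param cache per-cell histogram array from [cellHistogramCache()].
#' @param y numeric response.
#' @param config a \linkS4class{GAConfig}.
#' @param seed integer RNG seed for this run.
#' @param logEvery if positive, message the best RMSECV every that many
#'   generations.
#' @param memo optional environment used as a fitness memo table; pass
#'   the same environment to several runs to share evaluations (fitness
#'   is a pure function of the gene pattern, so sharing is safe).
#' @return A \linkS4class{GARunResult}.
#' @export
evolve <- function(cache, y, config, seed = 1L, logEvery = 0L,
                   memo = NULL) {
    set.seed(seed)
    nGenes <- dim(cache)[1]
    nim <- effectiveNim(config, nGenes)
    if (is.null(memo)) memo <- new.env(parent = emptyenv())
    n_eval <- 0L
    fit_of <- function(genes) {
        key <- paste(genes, collapse = "")
        val <- memo[[key]]
        if (is.null(val)) {
            val <- chromosomeFitness(genes, cache, y, config)
            memo[[key]] <- val
            n_eval <<- n_eval + 1L
        }
        val
    }
    P <- initPopulation(config, nGenes)
    fitness <- apply(P, 1L, fit_of)
    best_gen <- numeric(config@generations)
    ord <- order(fitness)
    best_genes <- P[ord[1], ]; best_fit <- fitness[ord[1]]
    n_elite <- min(ceiling(config@elitismRate * config@popSize),
                   config@popSize)
    for (g in seq_len(config@generations)) {
        ord <- order(fitness)
        newP <- P[ord[seq_len(n_elite)], , drop = FALSE]
        while (nrow(newP) < config@popSize) {
            par <- rouletteSelect(fitness)
            kids <- crossoverSinglePoint(P[par[1], ], P[par[2], ],
                                         config@crossoverRate)
            for (k in kids) {
                if (nrow(newP) >= config@popSize) break
                child <- repairChromosome(
                    mutateGenes(k, config@mutationRate), nim)
                newP <- rbind(newP, child)
            }
        }
        dimnames(newP) <- NULL
        P <- newP
        fitness <- apply(P, 1L, fit_of)
        gbest <- which.min(fitness)
        if (fitness[gbest] < best_fit) {
            best_fit <- fitness[gbest]
            best_genes <- P[gbest, ]
        }
        best_gen[g] <- best_fit
        if (logEvery > 0L && g %% logEvery == 0L)
            message("generation ", g, ": best RMSECV ",
                    signif(best_fit, 5))
    }
    new("GARunResult", bestGenes = as.integer(best_genes),
        bestFitness = best_fit, bestPerGeneration = best_gen,
        seed = as.integer(seed), nEvaluations = n_eval)
}

#' Best-of-n restarts
#'
#' Runs [evolve()] \code{nRestarts} times with independent seeds derived
#' from \code{masterSeed} and returns the best run plus the full set (for
#' RMSECV-distribution plots).
#'
#' @inheritParams evolve
#' @param masterSeed integer; restart seeds are drawn from it.
#' @return list with \code{best} (a \linkS4class{GARunResult}) and
#'   \code{runs} (list of all results, in restart order).
#' @export
runRestarts <- function(cache, y, config, masterSeed = 1L) {
    set.seed(masterSeed)
    seeds <- sample.int(.Machine$integer.max, config@nRestarts)
    memo <- new.env(parent = emptyenv())
    runs <- lapply(seeds, function(s)
        evolve(cache, y, config, seed = s, memo = memo))
    best <- runs[[which.min(vapply(runs, function(r) r@bestFitness,
                                   numeric(1)))]]
    list(best = best, runs = runs)
}

#' Monte-Carlo selection reliability
#'
#' Runs the GA \code{nMC} times with independent seeds and reports, for
#' each subimage, the fraction of runs in which it appears in the best
#' chromosome — a reliability map over the grid.
#'
#' @inheritParams runRestarts
#' @param nMC number of Monte-Carlo runs (>= 2).
#' @return numeric vector of selection frequencies in [0, 1], one per
#'   subimage.
#' @export
monteCarloReliability <- function(cache, y, config, nMC,
                                  masterSeed = 1L) {
    stopifnot(nMC >= 2L)
    set.seed(masterSeed)
    seeds <- sample.int(.Machine$integer.max, nMC)
    counts <- numeric(dim(cache)[1])
    for (s in seeds) {
        r <- evolve(cache, y, config, seed = s)
        counts <- counts + r@bestGenes
    }
    counts / nMC
}

#' Best-chromosome ROI table
#'
#' Translates the winning chromosome into 1-based (row, col) grid labels,
#' optionally annotated with retention-time frames computed from axis
#' ranges (x = first-dimension retention, left to right; y =
#' second-dimension retention, top to bottom).
#'
#' @param genes integer 0/1 vector.
#' @param grid the \linkS4class{ROIGrid} the genes index.
#' @param xRange,yRange optional numeric length-2 axis ranges (e.g.
#'   minutes for the first dimension, seconds for the second).
#' @return data.frame with columns \code{index, row, col} and, when axis
#'   ranges are supplied, \code{x_from, x_to, y_from, y_to}.
#' @export
selectedROITable <- function(genes, grid, xRange = NULL, yRange = NULL) {
    sel <- which(genes == 1L)
    tab <- gridBoundsTable(grid)[sel, , drop = FALSE]
    out <- tab[, c("index", "row", "col")]
    if (!is.null(xRange)) {
        K <- max(grid@colBounds)
        out$x_from <- xRange[1] + diff(xRange) * tab$x0 / K
        out$x_to <- xRange[1] + diff(xRange) * tab$x1 / K
    }
    if (!is.null(yRange)) {
        J <- max(grid@rowBounds)
        out$y_from <- yRange[1] + diff(yRange) * tab$y0 / J
        out$y_to <- yRange[1] + diff(yRange) * tab$y1 / J
    }
    rownames(out) <- NULL
    out
}
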