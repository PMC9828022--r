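Package: serialSFS
Title: Demographic Inference from Serially Sampled Site Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coalescent-based inference of recent changes in effective
    population size from folded multidimensional site frequency spectra
    (multiSFS) built from temporally spaced (serially sampled) cohorts.
    Provides a registry of seven single-population demographic models
    (constant size, single and double bottlenecks, instantaneous or
    exponential recovery, ancestral growth to carrying capacity), a
    serial-sampling coalescent simulator for expected spectra,
    simulation-based composite-likelihood fitting with multi-start
    direct search and AIC model selection, nonparametric bootstrap
    confidence intervals, pseudo-observed-data power analyses
    (model-selection confusion matrices), post-VCF genotype filtering
    and diversity statistics (windowed nucleotide diversity, observed
    and expected heterozygosity, F_IS), and census-side computations
    from age-structured stock-assessment tables (peak-spawning
    abundance, fecundity-weighted generation length, Ne/Nc ratios).
    Includes generators for synthetic genotype matrices and
    age-structured tables with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
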