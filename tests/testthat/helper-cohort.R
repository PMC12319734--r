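# Desk-scale synthetic cohort used by the acceptance tests: the cohort
# parameter distributions, platform geometries, noise floors and sampling
# rates are the package defaults; the problem size (trials per run, source
# grid spacing, TFS band step) is reduced so the full dual-platform
# pipeline runs on one CPU.

acceptanceCohortConfig <- function()
  runConfig(nSubjects = 15, nTrials = 8, seed = 1,
            gridSpacing = 0.016, tfsFreqs = seq(3, 99, 3), tfsBandwidth = 3,
            featureSets = "beta", nPermDiagonal = 10000, nPermGroup = 10000)

acceptanceCohort <- function() fixture("acceptanceCohort", function()
  runPipeline(acceptanceCohortConfig()))

# The same pipeline with between-subject variance switched off (all
# subjects share one parameter set); identification should fall to chance.
zeroVarianceCohort <- function() fixture("zeroVarianceCohort", function()
  runPipeline(runConfig(nSubjects = 15, nTrials = 4, seed = 2,
                        betweenScale = 0,
                        gridSpacing = 0.025, tfsFreqs = seq(10, 50, 10),
                        tfsBandwidth = 3, featureSets = "beta",
                        nPermDiagonal = 200, nPermGroup = 200)))
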