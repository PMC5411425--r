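# synkey

Hand grasping synergies as a behavioral biometric.

## The idea

When people reach out and grasp everyday objects, their finger joints do
not move independently: across objects, most of the kinematic variance is
captured by a handful of coordinated multi-joint patterns — *hand
synergies*. These patterns are stable within a person over days yet differ
between people, which makes them usable as a biometric key: something you
*do* rather than something you have.

`synkey` implements both verification channels end to end:

- **Movement synergies.** Ten joint angles (finger MCP/PIP, thumb MCP/IP)
  are recorded at 125 Hz while the subject grasps 25 objects spanning six
  grasp types. Each grasp's angular-velocity profile is segmented at 5% of
  peak speed, padded to 151 samples, and the 25 × 1510 session matrix is
  decomposed by truncated SVD into ranked synergies. Verification matches
  template and entry synergies by per-joint Pearson correlation, summed
  over a joint mask and maximized over ±20-sample shifts, accepting iff
  the score (percent of its maximum) strictly exceeds a threshold.
- **Postural synergies.** A movement synergy is integrated to a static end
  posture, gain-limited so all joints respect the range of motion and no
  fingertip folds past the palm on a planar virtual hand. The posture is
  photographed (here: rendered) against a chroma-key background; the
  silhouette's centroid-normalized radial outline is split into five
  per-finger segments at valley floors, and entries are accepted when the
  summed per-finger Euclidean error stays below a threshold.

The original human recordings are not publicly deposited, so the package
includes a seeded synthetic population generator — subject-specific
orthonormal velocity bases with a dominant first component, fixed
per-object mixing weights, smooth trial noise, and session-to-session
basis drift — that emulates the full enrollment/verification study without
external data.

## Worked example

Simulate a subject's registration session, extract their synergy key, and
verify an authentic and an imposter entry:

```r
library(synkey)

sub  <- makeSubject(seed = 1)                 # latent identity
recs <- simulateTrials(sub, repetitions = 1)  # one glove session
V <- buildVelocityMatrix(lapply(recs, function(r)
  padToFixed(segmentTrial(r), 151L)))
dim(V)
#> [1]   25 1510

s <- extractSynergies(V, n = 10)
s
#> SynergySet: 10 synergies (10 joints x 151 samples)
#>   variance fractions: 0.413 0.109 0.104 0.097 0.092 ...

verifySynergies(s, s)[c("score", "accept")]           # self
#> $score
#> [1] 100
#>
#> $accept
#> [1] TRUE

other <- extractSynergies(synkey:::.sessionMatrix(
  simulateTrials(makeSubject(seed = 2), repetitions = 1)), n = 10)
verifySynergies(s, other)[c("score", "accept")]       # imposter
#> $score
#> [1] 19.30479
#>
#> $accept
#> [1] FALSE
```

Run the full simulated verification study (10 subjects, 40 authentic and
180 imposter conditions) and compute the equal error rate:

```r
pop <- makePopulation(seed = 1)
scores <- collectScores(pop)
scores
#> ScoreSet: 40 true / 180 false conditions (mask 10 joints, synergies 1)
computeEER(scores)
#> EERResult: EER 0.00% at threshold 42.91 (441 grid points)
```

Turn the first synergy into a posture, render it, and compare an authentic
replication with an imposter's attempt:

```r
sg <- selectGain(synergies(s)[[1]])
tmpl <- renderPosture(sg$posture, splayOffsets = sub$splayOffsets,
                      jitterSd = 2, seed = 1)
auth <- renderPosture(sg$posture, splayOffsets = sub$splayOffsets,
                      jitterSd = 2, seed = 2)
imp  <- renderPosture(sg$posture,
                      splayOffsets = makeSubject(seed = 9)$splayOffsets,
                      jitterSd = 5, seed = 3)
postureVerify(tmpl, auth)$total
#> [1] 8.626731
postureVerify(tmpl, imp)$total
#> [1] 21.06118
```

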