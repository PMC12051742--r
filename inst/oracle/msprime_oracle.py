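"""Independent coalescent oracle used by the test suite.

Simulates a two-population isolation-with-migration model with exponential
growth in msprime and writes per-replicate TMRCA and segregating-site counts
to a TSV, for distributional comparison (KS) against the package's own
structured-coalescent engine.

Usage: python msprime_oracle.py SEED N_REPS OUT_TSV
Model (times in generations, sizes diploid):
  popA: 5 diploids, Ne 10000, growth 5e-4 since generation 2000
  popB: 5 diploids, Ne 20000, constant
  split into ANC (Ne 15000) at generation 8000
  migration (backward lineage rates) A<->B 1e-4 until the split
  locus: 2000 bp, mu 3.18e-9, no recombination
"""
import sys

import msprime

def main():
    seed, n_reps, out = int(sys.argv[1]), int(sys.argv[2]), sys.argv[3]
    dem = msprime.Demography()
    # initial_size is the size at time 0; growth_rate>0 shrinks it backward
    dem.add_population(name="A", initial_size=10000, growth_rate=5e-4)
    dem.add_population(name="B", initial_size=20000)
    dem.add_population(name="ANC", initial_size=15000)
    dem.add_population_parameters_change(time=2000, population="A",
                                         growth_rate=0.0)
    dem.set_migration_rate("A", "B", 1e-4)  # lineages from A move to B
    dem.set_migration_rate("B", "A", 1e-4)
    dem.add_population_split(time=8000, derived=["A", "B"], ancestral="ANC")
    dem.sort_events()
    rows = []
    reps = msprime.sim_ancestry(
        samples={"A": 5, "B": 5}, demography=dem, sequence_length=2000,
        recombination_rate=0, ploidy=2, num_replicates=n_reps,
        random_seed=seed)
    rng_seed = seed
    for ts in reps:
        rng_seed += 1
        mts = msprime.sim_mutations(ts, rate=3.18e-9, random_seed=rng_seed,
                                    discrete_genome=False)
        tmrca = max(t.time(t.root) for t in ts.trees())
        rows.append((tmrca, mts.num_sites))
    with open(out, "w") as fh:
        fh.write("tmrca\tn_sites\n")
        for t, s in rows:
            fh.write(f"{t}\t{s}\n")

if __name__ == "__main__":
    main()
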