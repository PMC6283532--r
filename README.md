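# devgraph

Deviation-value profiling of country nutrition and health indicators, for
diagnosing the **double burden of malnutrition** — undernutrition and
overnutrition coexisting in the same population — at the country level.

The audience is public-health analysts who assemble country ×
indicator tables from agency sources (UNICEF child nutrition, WHO NCD risk
factors and mortality, WASH coverage, World Bank socioeconomic data) and
want to read one country's position against its economic peers across the
whole life course, from gestation to death.

## The method

Every indicator is put on a common **deviation value** (T-score) scale
across the countries reporting it:

1. Box–Cox normalization, `y = ((x+s)^λ − 1)/λ` (log at λ = 0), with λ
   maximizing the profile log-likelihood and a shift `s` guaranteeing
   positivity;
2. T-score standardization, `T = 50 + 10·(y − ȳ)/s_y` (sample SD) — mean
   50 and SD 10 by construction;
3. **ceiling indicators** (near-100% literacy-like rates, where a power
   transform cannot unpile the top) scored by rank instead:
   `p = (rank − 0.5)/n`, `T = 50 + 10·Φ⁻¹(p)`;
4. **orientation** so higher always means more desirable: lower-desirable
   indicators (stunting, smoking, NCD mortality) are reflected about the
   reference, `T ↦ 100 − T`.

A score of 50 is the international reference; 60 is one standard deviation
better than average, 40 one worse. Scores are banded for narration
(`very_low` < 35, `low` 35–45, `middle` 45–55, `high` 55–72, `very_high`
≥ 72), grouped by World Bank income class for comparison among economic
peers, classified by distribution modality (normal / distorted / bimodal /
trimodal), and rendered per country as a **deviation graph** grouped by
life stage. A synthetic-data generator reproduces all the distribution
shapes the method must handle, so the whole pipeline is testable offline.

## Worked example

```r
library(devgraph)

tab <- generate_table(generator_config(seed = 2024))  # 194 countries, 10 indicators
dm  <- score_table(tab)                               # Box-Cox + T-score / percentile
pr  <- build_profile(dm, tab, "C150")
flag_extremes(pr)
#> # A tibble: 3 × 4
#>   indicator        direction value raw_reading
#>   <chr>            <chr>     <dbl>       <dbl>
#> 1 under5_mortality weakness   36.6        63.4
#> 2 adult_literacy   strength   62.2        62.2
#> 3 life_expectancy  strength   60.5        60.5
```

Country C150's under-5 mortality reads 63.4 in raw direction (high
mortality); oriented so higher = better it scores 36.6, more than one SD
below the reference — a weakness. Literacy (62.2, percentile-scored
because it piles up near 100%) and life expectancy (60.5) are strengths.

```r
render_deviation_graph(pr, "C150.png")   # bar chart by life stage + sidecar CSV
summarize_group(dm, tab, "low")          # per-indicator mean/min/max in a class
#>   indicator                mean   min   max n_with_data
#> 1 life_expectancy          52.7  33.5  73.4          34
#> 2 exclusive_breastfeeding  49.1  27.6  73.9          32
#> ...
```

For real data, supply two CSVs — a table (`country,income,<indicators>`)
and a registry (`id,name,life_stage,polarity,ceiling,units`; a 53-indicator
template ships at `example_registry()`) — to `read_country_table()`. A thin
CLI over the same functions lives at `inst/cli/devgraph.R`
(`generate` / `score` / `profile` subcommands).

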