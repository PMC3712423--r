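# Hypothesized male path model: aggressiveness and exploration acting on
# fledgling production via provisioning rates, lay date and brood size.
1: aggression -> exploration
2: aggression -> feed_own
3: aggression -> fledgling_no
4: aggression -> fledgling_mass
5: aggression -> lay_date
6: exploration -> feed_own
7: exploration -> fledgling_no
8: exploration -> fledgling_mass
9: exploration -> lay_date
10: feed_own -> feed_partner
11: feed_own -> fledgling_no
12: feed_own -> fledgling_mass
13: feed_partner -> fledgling_no
14: feed_partner -> fledgling_mass
15: lay_date -> brood_size
16: brood_size -> feed_own
17: brood_size -> feed_partner
18: brood_size -> fledgling_no
19: brood_size -> fledgling_mass
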