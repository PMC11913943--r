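from,to,interval,area_ha
grasses,grasses,2009-2014,137.98
grasses,woody,2009-2014,58.63
woody,grasses,2009-2014,10.18
woody,woody,2009-2014,121.70
grasses,bare,2009-2014,16.07
bare,grasses,2009-2014,5.21
grasses,grasses,2014-2019,104.85
grasses,woody,2014-2019,47.24
woody,grasses,2014-2019,8.74
woody,woody,2014-2019,172.06
grasses,bare,2014-2019,1.41
bare,grasses,2014-2019,10.10
grasses,grasses,2019-2023,97.19
grasses,woody,2019-2023,44.10
woody,grasses,2019-2023,6.96
woody,woody,2019-2023,217.23
grasses,bare,2019-2023,1.08
bare,grasses,2019-2023,3.41
grasses,grasses,2009-2023,80.52
grasses,woody,2009-2023,130.69
woody,grasses,2009-2023,2.78
woody,woody,2009-2023,130.07
grasses,bare,2009-2023,0.43
bare,grasses,2009-2023,6.20
grasses,grasses,2023-2028,44.84
grasses,woody,2023-2028,40.68
woody,grasses,2023-2028,20.87
woody,woody,2023-2028,239.39
grasses,bare,2023-2028,3.99
bare,grasses,2023-2028,0.64
grasses,grasses,2028-2033,37.07
grasses,woody,2028-2033,28.97
woody,grasses,2028-2033,8.41
woody,woody,2028-2033,272.55
grasses,bare,2028-2033,0.86
bare,grasses,2028-2033,0.61
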