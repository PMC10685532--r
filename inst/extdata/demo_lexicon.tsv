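term	strength
راضی	4
خوشحال	4
صمیمی	3
مهربان	3
خوب	3
عالی	5
تمیز	3
سریع	2
امیدوار	3
دلسوز	3
مرتب	2
مودب	2
خوشرو	3
صبور	2
دقیق	2
منظم	2
راحت	2
مفید	2
ممنون	2
سپاسگزار	3
قوی	2
شاد	3
خندان	2
امن	2
گرم	1
تازه	2
خوشمزه	3
لذیذ	3
پاکیزه	3
درخشان	2
موفق	3
سلامت	2
خوشبین	3
قشنگ	2
زیبا	3
بد	-3
کثیف	-3
ناراحت	-3
نگران	-2
ضعیف	-2
افتضاح	-5
وحشتناک	-4
ناامید	-3
عصبانی	-3
پرهزینه	-2
شلوغ	-2
کند	-1
سرد	-1
دیر	-2
خسته	-2
آلوده	-2
خراب	-3
بدبو	-2
دردناک	-3
ترسناک	-3
طولانی	-2
تلخ	-1
کهنه	-2
شکسته	-2
تاریک	-1
بداخلاق	-3
غمگین	-3
گریان	-2
مایوس	-3
پژمرده	-2
ناامن	-2
مضطرب	-2
دلخور	-2
ناراضی	-4
معطل	-2
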